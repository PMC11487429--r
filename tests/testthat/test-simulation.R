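test_that("emit_pair: isotropy and non-colinearity FWHM", {
  set.seed(31)
  n <- 1e5
  pts <- matrix(0, n, 3)
  dd <- emit_pair(pts, noncolinearity_deg_fwhm = 0.5)
  # cos(theta) of the first photon uniform on [-1, 1]
  ks <- suppressWarnings(stats::ks.test(dd$dir1[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 1e-3)
  # deviation angle from perfect anti-parallelism: half-normal with
  # sigma = FWHM/2.355; sqrt(mean(delta^2)) estimates sigma
  cosd <- -rowSums(dd$dir1 * dd$dir2)
  delta <- acos(pmin(1, cosd)) * 180 / pi
  fwhm_est <- sqrt(mean(delta^2)) * 2 * sqrt(2 * log(2))
  se <- 0.5 / sqrt(2 * n)  # ~MC error of the sigma estimate, scaled
  expect_lt(abs(fwhm_est - 0.5), 5 * se + 0.01)
  # FWHM 0: exactly anti-parallel
  d0 <- emit_pair(matrix(0, 10, 3), 0)
  expect_equal(d0$dir2, -d0$dir1)
  # unit norms
  expect_equal(rowSums(dd$dir2^2), rep(1, n), tolerance = 1e-12)
})

test_that("decay times form a Poisson process", {
  set.seed(32)
  t1 <- generate_decay_times(1000, 10)
  expect_true(!is.unsorted(t1))
  expect_lt(abs(length(t1) - 1e4), 5 * 100)
  gaps <- diff(t1) / 1e9
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", 1000))
  expect_gt(ks$p.value, 1e-3)
  expect_length(generate_decay_times(0, 5), 0)
})

test_that("water transmission and Compton kinematics closed forms", {
  set.seed(33)
  n <- 1e5
  slab <- analytic_phantom(list(prim_box(c(50, 0, 0), c(100, 500, 500), 0, "water")),
                           "air")
  tr <- transport_phantom(matrix(rep(c(-1, 0, 0), each = n), n),
                          matrix(rep(c(1, 0, 0), each = n), n),
                          rep(511, n), slab)
  p_exp <- exp(-0.958)  # mu 0.0958/cm over 10 cm
  p_obs <- mean(tr$escaped & tr$nscatter == 0)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  # air phantom: always escapes unscattered
  air <- analytic_phantom(list(prim_box(c(0, 0, 0), 100, 0, "air")), "air")
  ta <- transport_phantom(matrix(0, 100, 3),
                          matrix(rep(c(0, 0, 1), each = 100), 100),
                          rep(511, 100), air)
  expect_true(all(ta$escaped) && all(ta$nscatter == 0))
  # scattered energies satisfy the Compton relation: E' = E/(1+a(1-cos t)),
  # checked through the deflection angle of single-scattered photons
  sc <- tr$nscatter == 1 & tr$escaped
  ct <- tr$dir[sc, 1]                    # initial direction was +x
  epred <- 511 / (1 + (511 / 511) * (1 - ct))
  expect_equal(tr$energy[sc], epred, tolerance = 1e-9)
  # 90-degree scatter at 511 keV -> 255.5 keV
  expect_equal(511 / (2 - cos(pi / 2)), 255.5)
  # mean scattering cosine vs the numeric Klein-Nishina integral, using a
  # thin (5 mm) slab so escape barely biases the angular distribution
  thin <- analytic_phantom(list(prim_box(c(2.5, 0, 0), c(5, 500, 500), 0,
                                         "water")), "air")
  m <- 2e5
  tt <- transport_phantom(matrix(rep(c(-1, 0, 0), each = m), m),
                          matrix(rep(c(1, 0, 0), each = m), m), rep(511, m),
                          thin)
  sc1 <- tt$nscatter == 1 & tt$escaped
  ct1 <- tt$dir[sc1, 1]
  expect_gt(sum(sc1), 3000)
  expect_lt(abs(mean(ct1) - kn_mean_cos(511)),
            3 * sd(ct1) / sqrt(sum(sc1)) + 0.01)
})

test_that("LYSO interaction probability and crystal-length monotonicity", {
  set.seed(34)
  n <- 4e4
  shoot <- function(len) {
    g <- build_flat_panel(crystal_spec(3, len))
    pos <- cbind(0, runif(n, -140, 140), runif(n, -140, 140))
    det <- transport_detector(pos, matrix(rep(c(1, 0, 0), each = n), n),
                              rep(511, n), g)
    length(unique(det$photon)) / n
  }
  p10 <- shoot(10)
  p_exp <- 1 - exp(-0.87)
  expect_lt(abs(p10 - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  expect_gt(p10, shoot(5))
})

test_that("detector transport conserves energy per photon", {
  set.seed(35)
  n <- 5000
  g <- build_flat_panel(crystal_spec(3, 10))
  pos <- cbind(0, runif(n, -100, 100), runif(n, -100, 100))
  dir <- matrix(rep(c(1, 0, 0), each = n), n)
  det <- transport_detector(pos, dir, rep(511, n), g)
  dep <- rep(0, n)
  agg <- det[, .(E = sum(edep)), by = photon]
  dep[agg$photon] <- agg$E
  expect_equal(dep + attr(det, "escaped_energy"), rep(511, n), tolerance = 1e-9)
})

test_that("acquisition: duration scaling and determinism", {
  g <- build_flat_panel(crystal_spec(3, 10))
  ph <- point_source_with_background(c(0, 0, 0), bg_activity_kBq = 0,
                                     source_activity_Bq = 1e4)
  set.seed(36)
  a1 <- run_acquisition(ph, g, n_decays = 2e4)
  set.seed(36)
  a2 <- run_acquisition(ph, g, n_decays = 2e4)
  expect_identical(a1$interactions, a2$interactions)
  set.seed(37)
  a3 <- run_acquisition(ph, g, n_decays = 4e4)
  expect_lt(abs(nrow(a3$interactions) / nrow(a1$interactions) - 2), 0.2)
  a0 <- run_acquisition(ph, g, duration_s = 0)
  expect_equal(nrow(a0$interactions), 0L)
})

test_that("central-source geometric pair efficiency matches numerical integration", {
  # brute-force direction-space integral for two opposing 30x30 panels at
  # 40 cm: fraction of isotropic LOR directions hitting both panels
  nth <- 400
  u <- seq(-1 + 1 / nth, 1 - 1 / nth, length.out = nth)     # cos(theta)
  phi <- seq(0, 2 * pi, length.out = 2 * nth + 1)[-1]
  hit <- 0
  for (cu in u) {
    su <- sqrt(1 - cu^2)
    dx <- su * cos(phi); dy <- su * sin(phi)
    ok <- abs(dx) > 1e-9
    t <- 200 / abs(dx[ok])
    inside <- abs(dy[ok] * t) <= 150 & abs(cu * t) <= 150
    hit <- hit + sum(inside)
  }
  frac_oracle <- hit / (nth * 2 * nth)
  set.seed(38)
  g2 <- build_flat_panel(crystal_spec(3, 10), n_panels = 2)
  n <- 2e5
  dd <- emit_pair(matrix(0, n, 3), 0)
  hits <- panelpet:::line_hits_detector(matrix(0, n, 3), dd$dir1, g2, margin = 0)
  frac_mc <- mean(hits)
  expect_lt(abs(frac_mc - frac_oracle), 0.01 * frac_oracle + 3 * sqrt(frac_oracle / n))
})
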