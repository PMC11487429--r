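make_ints <- function(...) {
  data.table::data.table(...)
}

test_that("readout grouping policies position and sum deposits", {
  g <- build_flat_panel(crystal_spec(3, 10))
  # crystals (row 1, col 1) and (row 2, col 2) of panel 1: same submodule
  idA <- 1L
  idB <- 1L * g$n_side + 2L
  ints <- make_ints(event = c(1L, 1L), crystal = c(idA, idB),
                    edep = c(340, 171), t = c(0, 0.1), scat = c(FALSE, FALSE))
  # submodule level, winner-take-all: one 511 keV single at the 340 crystal
  s <- group_to_singles(ints, g, level = "submodule", integration_ns = 2)
  expect_equal(nrow(s), 1L)
  expect_equal(s$energy, 511)
  expect_equal(s$crystal, idA)
  expect_equal(s$t, 0)
  # crystal level: two singles that will both fail the energy window
  s2 <- group_to_singles(ints, g, level = "crystal", integration_ns = 2)
  expect_equal(sort(s2$energy), c(171, 340))
  expect_equal(nrow(apply_energy_window(s2)), 0L)
  # single photoelectric deposit
  s3 <- group_to_singles(make_ints(event = 1L, crystal = 5L, edep = 511,
                                   t = 2, scat = FALSE), g)
  expect_equal(s3$energy, 511)
  # energy-centroid: 340/171 in adjacent crystals snaps to a crystal of the group
  s4 <- group_to_singles(ints, g, level = "submodule",
                         energy_policy = "centroid", integration_ns = 2)
  expect_equal(s4$energy, 511)
  expect_true(s4$crystal %in% c(idA, idB))
  # deposits separated by more than the integration window stay separate
  far <- make_ints(event = c(1L, 1L), crystal = c(idA, idB),
                   edep = c(300, 200), t = c(0, 10), scat = c(FALSE, FALSE))
  expect_equal(nrow(group_to_singles(far, g, level = "submodule")), 2L)
})

test_that("energy blur: 10% FWHM at 511 keV, mean preserved, identity at 0", {
  set.seed(41)
  n <- 1e5
  e <- blur_energy(rep(511, n), 0.10)
  expect_lt(abs(sd(e) * 2 * sqrt(2 * log(2)) / 511 - 0.10), 0.002)
  expect_lt(abs(mean(e) - 511), 0.5)
  expect_identical(blur_energy(c(100, 511), 0), c(100, 511))
  # window acceptance of a blurred photopeak ~ 0.9995
  acc <- mean(e >= 435 & e <= 585)
  sig <- 0.10 * 511 / (2 * sqrt(2 * log(2)))
  acc_exp <- pnorm((585 - 511) / sig) - pnorm((435 - 511) / sig)
  expect_lt(abs(acc - acc_exp), 3 * sqrt(acc_exp * (1 - acc_exp) / n))
  # a 255 keV deposit never enters the 435-585 window
  e255 <- blur_energy(rep(255.5, n), 0.10)
  expect_equal(sum(e255 >= 435), 0L)
})

test_that("time blur gives pair dt FWHM equal to the CTR", {
  set.seed(42)
  n <- 1e5
  t1 <- blur_time(rep(0, n), 75)
  t2 <- blur_time(rep(0, n), 75)
  fwhm_ps <- sd(t1 - t2) * 1e3 * 2 * sqrt(2 * log(2))
  expect_lt(abs(fwhm_ps - 75), 1.5)      # ~3 sigma of the sd estimate
  expect_identical(blur_time(c(1, 2), 0), c(1, 2))
  # single-detector sigma at CTR 214: 214/2.355/sqrt(2) ~ 64.3 ps
  expect_equal(214 / (2 * sqrt(2 * log(2))) / sqrt(2), 64.26, tolerance = 1e-3)
})

test_that("coincidence sorter equals the brute-force all-pairs oracle", {
  set.seed(43)
  g <- build_flat_panel(crystal_spec(3, 10))
  for (rep in 1:1000) {
    n <- sample(2:25, 1)
    t <- sort(runif(n, 0, n * 1.5))
    panel <- sample(1:4, n, replace = TRUE)
    got <- cpp_sort_coincidences(t, panel, 2, 0L, 4L, 4L)
    want <- oracle_sort(t, panel, 2, "panel")
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(as.matrix(got)), unname(want))
    }
  }
  # ring mode with min sector difference
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    t <- sort(runif(n, 0, n))
    sec <- sample(1:19, n, replace = TRUE)
    got <- cpp_sort_coincidences(t, sec, 4.7, 1L, 19L, 4L)
    want <- oracle_sort(t, sec, 4.7, "ring", 19, 4)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) expect_equal(unname(as.matrix(got)), unname(want))
  }
})

test_that("sorter classifies truth and enforces ordering", {
  g <- build_flat_panel(crystal_spec(3, 10))
  s <- data.table::data.table(
    crystal = c(1L, g$per_panel + 1L, 2L, 2L * g$per_panel + 5L),
    energy = rep(511, 4),
    t = c(0, 0.5, 100, 100.8),
    event = c(1L, 1L, 2L, 3L),
    scat = c(FALSE, FALSE, FALSE, TRUE),
    panel = c(1L, 2L, 1L, 3L))
  co <- sort_coincidences(s, g, coincidence_policy(window_ns = 2))
  expect_equal(nrow(co), 2L)
  expect_equal(co$class, c("true", "random"))
  # same-event pair with a phantom-scattered photon is "scattered"
  s2 <- data.table::copy(s)[1:2][, `:=`(event = c(7L, 7L), scat = c(TRUE, FALSE))]
  expect_equal(sort_coincidences(s2, g)$class, "scattered")
  # same panel pair is dropped
  s3 <- data.table::copy(s)[1:2][, panel := c(1L, 1L)]
  expect_equal(nrow(sort_coincidences(s3, g)), 0L)
  expect_error(sort_coincidences(data.table::copy(s)[c(3, 1, 2, 4)], g), "sorted")
})

test_that("count rates partition coincidences", {
  co <- data.table::data.table(class = c(rep("true", 80), rep("scattered", 15),
                                         rep("random", 5)))
  r <- count_rates(co, 10)
  expect_equal(r$T, 8)
  expect_equal(r$S, 1.5)
  expect_equal(r$R, 0.5)
  expect_equal(r$T + r$S + r$R, nrow(co) / 10)
})
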