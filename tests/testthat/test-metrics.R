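test_that("3D Gaussian fit: exact recovery, offset identifiability, noise bias", {
  g <- image_grid_centered(0.5, 40)
  truth <- list(A = 10, center = c(0.3, -0.7, 0.1), sigma = c(1.0, 1.2, 0.8))
  img <- synth_gaussian(g, truth$A, truth$center, truth$sigma)
  f <- fit_gaussian_3d(img)
  expect_true(f$converged)
  expect_equal(f$sigma, truth$sigma, tolerance = 1e-6)
  expect_equal(f$fwhm[1], 2 * sqrt(2 * log(2)) * 1.0, tolerance = 1e-6)
  expect_equal(f$center, truth$center, tolerance = 1e-6)
  # constant offset recovered, sigma unchanged
  img2 <- synth_gaussian(g, truth$A, truth$center, truth$sigma, C = 5)
  f2 <- fit_gaussian_3d(img2)
  expect_equal(f2$C, 5, tolerance = 1e-6)
  expect_equal(f2$sigma, truth$sigma, tolerance = 1e-5)
  # 5% noise: sigma recovered within 3%
  set.seed(61)
  noisy <- img$data + rnorm(length(img$data), 0, 0.05 * truth$A)
  f3 <- suppressWarnings(fit_gaussian_3d(image_volume(noisy, g)))
  expect_true(all(abs(f3$sigma / truth$sigma - 1) < 0.03))
})

test_that("NECR identities and TOF gain", {
  expect_equal(necr(100, 0, 0), 100)
  expect_equal(necr(80, 15, 5), 64)
  expect_equal(necr(0, 0, 0), 0)
  set.seed(62)
  for (i in 1:200) {
    T <- runif(1, 0, 1e5); S <- runif(1, 0, 1e5); R <- runif(1, 0, 1e5)
    expect_equal(necr(T, S, R), T^2 / (T + S + R))
    expect_lte(necr(T, S, R), T)
    ctr <- runif(1, 50, 500)
    expect_equal(necr_tof(necr(T, S, R), 200, ctr),
                 2 * 0.2 / (299792458 * ctr * 1e-12) * necr(T, S, R))
  }
  expect_equal(necr_tof(100, 200, 75), 17.79 * 100, tolerance = 1e-3)
  expect_equal(necr_tof(1, 200, 150) * 2, necr_tof(1, 200, 75))
  expect_equal(necr_tof(0, 200, 75), 0)
  expect_error(necr_tof(10, 200, 0), "undefined")
})

test_that("normalization correction: identity on constants, flattens ramps", {
  g <- image_grid_centered(2, 16)
  img <- image_volume(array(runif(prod(g$dim)), g$dim), g)
  hom1 <- image_volume(array(1, g$dim), g)
  expect_equal(normalize_by_homogeneous(img, hom1)$data, img$data,
               tolerance = 1e-12)
  hom2 <- image_volume(array(2, g$dim), g)
  expect_equal(normalize_by_homogeneous(img, hom2)$data, img$data,
               tolerance = 1e-12)
  # linear sensitivity ramp exactly flattened for a uniform phantom image
  ramp <- array(rep(seq(1, 3, length.out = g$dim[1]), times = prod(g$dim[2:3])),
                g$dim)
  out <- normalize_by_homogeneous(image_volume(5 * ramp, g),
                                  image_volume(ramp, g), filter_fwhm_mm = 0)
  expect_equal(out$data, array(5 * mean(ramp), g$dim), tolerance = 1e-9)
  expect_error(normalize_by_homogeneous(img, image_volume(array(1, c(8, 16, 16)),
                                                          image_grid(2, c(8, 16, 16), g$origin))),
               "grids")
})

test_that("IQ analysis: definitional limits on synthetic images", {
  ph <- nema_iq_phantom()
  g <- image_grid_centered(3, 121)
  truth <- voxelize(ph, g, supersample = 2)
  iq <- nema_iq_analysis(truth, attr(ph, "sphere_centers"),
                         attr(ph, "sphere_diameters"), ratio = 4)
  # noiseless ground truth: large-sphere contrast ~100%, variability ~0
  expect_gt(iq$contrast_pct[6], 95)
  expect_lt(iq$contrast_pct[6], 101)
  expect_lt(iq$variability_pct[6], 1.5)
  expect_true(all(diff(iq$contrast_pct) > -5))  # partial volume hits small spheres
  # C_H == C_B gives zero contrast
  flat <- image_volume(array(1, g$dim), g)
  iq0 <- nema_iq_analysis(flat, attr(ph, "sphere_centers"),
                          attr(ph, "sphere_diameters"), ratio = 4)
  expect_equal(iq0$contrast_pct, rep(0, 6), tolerance = 1e-9)
  expect_equal(iq0$variability_pct, rep(0, 6), tolerance = 1e-9)
})

test_that("hand-computable two-ROI contrast", {
  # C_H = 4, C_B = 1, ratio 4 -> Q = 100%
  expect_equal(100 * (4 / 1 - 1) / (4 - 1), 100)
})

test_that("contrast-at-variability interpolation", {
  curve <- data.frame(filter_fwhm_mm = c(0, 2), contrast_pct = c(80, 70),
                      variability_pct = c(4, 6))
  # bracketed: (N,Q) = (4,80),(6,70) -> 75 at N=5 (orders by filter width:
  # N falls with filter, here constructed rising to test the bracketing)
  expect_equal(contrast_at_variability(curve, 5), 75)
  exact <- data.frame(filter_fwhm_mm = c(0, 1, 2), contrast_pct = c(80, 74, 70),
                      variability_pct = c(8, 5, 3))
  expect_equal(contrast_at_variability(exact, 5), 74)
  expect_error(contrast_at_variability(exact, 20), "refused")
})

test_that("SSIM: identity, symmetry, oracle equivalence", {
  set.seed(63)
  x <- matrix(runif(30 * 28), 30, 28)
  expect_equal(ssim(x, x, data_range = 1), 1, tolerance = 1e-12)
  y <- x + matrix(rnorm(30 * 28, 0, 0.1), 30, 28)
  expect_equal(ssim(x, y, data_range = 1), ssim(y, x, data_range = 1),
               tolerance = 1e-12)
  for (i in 1:3) {
    a <- matrix(runif(26 * 26), 26, 26)
    b <- matrix(runif(26 * 26), 26, 26)
    expect_equal(ssim(a, b, data_range = 1), oracle_ssim(a, b, 1),
                 tolerance = 1e-6)
  }
  expect_error(ssim(x, t(x)), "dimensions")
})

test_that("ssim_curve crops to reference support and sweeps filters", {
  set.seed(64)
  g <- image_grid_centered(1, c(40, 40, 8))
  ph <- analytic_phantom(list(prim_cylinder(c(0, 0, 0), 12, 8, activity_kBq_mL = 4)),
                         "air")
  ref <- voxelize(ph, g, 2)
  noisy <- image_volume(ref$data + array(rnorm(length(ref$data), 0, 1), g$dim), g)
  sc <- ssim_curve(noisy, ref, filter_fwhms_mm = c(0, 2, 4))
  expect_equal(nrow(sc), 3)
  expect_true(all(sc$ssim >= -1 & sc$ssim <= 1))
  # identical inputs give SSIM 1 at zero filter
  sc1 <- ssim_curve(ref, ref, filter_fwhms_mm = 0)
  expect_equal(sc1$ssim, 1, tolerance = 1e-9)
})

test_that("gaussian_fit flags non-convergence on pathological input", {
  g <- image_grid_centered(1, 8)
  flat <- image_volume(array(1, g$dim), g)
  f <- suppressWarnings(fit_gaussian_3d(flat))
  expect_false(isTRUE(f$converged) && is.finite(f$A) && f$A > 0.5)
})
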