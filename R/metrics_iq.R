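# NEMA NU 2-2018 image-quality analysis: normalization correction, 10x
# in-plane upsampling, hot-sphere percent contrast and background
# variability over 60 background ROIs.

# 12 background ROI centers (mm, central-slice template), kept >= 15 mm
# from the phantom wall and clear of the spheres and the lung insert.
IQ_BG_ROI_XY <- matrix(c(
   100,   0,  -100,    0,
    60,  70,   -60,   70,
    60, -70,   -60,  -70,
     0,  85,     0,  -85,
   110,  30,  -110,   30
), ncol = 2, byrow = TRUE)
IQ_BG_ROI_XY <- rbind(IQ_BG_ROI_XY, c(110, -30), c(-110, -30))

#' Normalization correction by a homogeneous acquisition
#'
#' Divides an image by the heavily smoothed reconstruction of a
#' homogeneous activity cube and multiplies by the mean of the smoothed
#' image, flattening the position-dependent sensitivity. Voxels where the
#' homogeneous image falls below 1% of its mean are set to zero.
#'
#' @param image,homog_image [image_volume()]s on the same grid.
#' @param filter_fwhm_mm Smoothing applied to the homogeneous image.
#' @return Corrected [image_volume()].
#' @export
normalize_by_homogeneous <- function(image, homog_image, filter_fwhm_mm = 15) {
  if (!all(image$grid$dim == homog_image$grid$dim) ||
      image$grid$voxel != homog_image$grid$voxel)
    stop("image and homogeneous image are on different grids")
  # edge-renormalized smoothing: constants stay constant at the boundary
  sig <- filter_fwhm_mm / FWHM_SIGMA / image$grid$voxel
  h <- if (sig > 0) {
    num <- cpp_gauss_filter3(as.numeric(homog_image$data), image$grid$dim, sig)
    den <- cpp_gauss_filter3(rep(1, prod(image$grid$dim)), image$grid$dim, sig)
    array(num / den, image$grid$dim)
  } else homog_image$data
  m <- mean(h)
  out <- ifelse(h > 0.01 * m, image$data / h * m, 0)
  image_volume(array(out, image$grid$dim), image$grid)
}

upsample_xy <- function(slice, factor = 10) {
  slice[rep(seq_len(nrow(slice)), each = factor),
        rep(seq_len(ncol(slice)), each = factor)]
}

roi_mean <- function(up, grid, factor, cx, cy, diameter) {
  # pixel centers of the upsampled in-plane grid
  px <- grid$origin[1] + (seq_len(grid$dim[1] * factor) - 0.5) * grid$voxel / factor
  py <- grid$origin[2] + (seq_len(grid$dim[2] * factor) - 0.5) * grid$voxel / factor
  dx <- outer(px - cx, rep(1, length(py)))
  dy <- outer(rep(1, length(px)), py - cy)
  inside <- dx^2 + dy^2 <= (diameter / 2)^2
  if (!any(inside)) stop("ROI at (", cx, ", ", cy, ") lies outside the image")
  mean(up[inside])
}

#' NEMA image-quality metrics
#'
#' Percent contrast `Q = 100 ((C_H/C_B) - 1) / (ratio - 1)` per hot sphere
#' and background variability `N = 100 SD_B / C_B` over 60 background ROIs
#' (12 in-plane positions x 5 slices at 0, +-10, +-20 mm), with ROI
#' diameters equal to the sphere inner diameters, all drawn on the
#' 10x-upsampled in-plane grid.
#'
#' @param image Normalized (optionally filtered) [image_volume()].
#' @param sphere_centers 6 x 3 matrix of sphere centers (mm).
#' @param sphere_diameters Inner diameters (mm).
#' @param ratio Sphere-to-background activity ratio (4 for the standard
#'   fill).
#' @param upsample In-plane upsampling factor.
#' @return data.frame: `diameter_mm`, `contrast_pct`, `variability_pct`.
#' @export
nema_iq_analysis <- function(image, sphere_centers, sphere_diameters,
                             ratio = 4, upsample = 10) {
  g <- image$grid
  zc <- grid_centers(g, 3)
  central <- which.min(abs(zc - sphere_centers[1, 3]))
  bg_slices <- vapply(sphere_centers[1, 3] + c(-20, -10, 0, 10, 20),
                      function(z) which.min(abs(zc - z)), 0L)
  ups <- lapply(unique(c(central, bg_slices)), function(k)
    upsample_xy(image$data[, , k], upsample))
  names(ups) <- as.character(unique(c(central, bg_slices)))
  out <- data.frame(diameter_mm = sphere_diameters, contrast_pct = NA_real_,
                    variability_pct = NA_real_)
  for (s in seq_along(sphere_diameters)) {
    d <- sphere_diameters[s]
    ch <- roi_mean(ups[[as.character(central)]], g, upsample,
                   sphere_centers[s, 1], sphere_centers[s, 2], d)
    cb <- vapply(bg_slices, function(k) {
      up <- ups[[as.character(k)]]
      vapply(seq_len(nrow(IQ_BG_ROI_XY)), function(r)
        roi_mean(up, g, upsample, IQ_BG_ROI_XY[r, 1], IQ_BG_ROI_XY[r, 2], d),
        0)
    }, numeric(nrow(IQ_BG_ROI_XY)))
    cbm <- mean(cb)
    out$contrast_pct[s] <- 100 * (ch / cbm - 1) / (ratio - 1)
    out$variability_pct[s] <- 100 * sd(as.numeric(cb)) / cbm
  }
  out
}

#' Interpolate contrast at a target background variability
#'
#' Linear interpolation of contrast versus variability between the two
#' filter widths bracketing the target; refuses to extrapolate.
#'
#' @param curve data.frame with `filter_fwhm_mm`, `contrast_pct`,
#'   `variability_pct` (one sphere size), e.g. from [iq_filter_sweep()].
#' @param target_pct Target variability (default 5).
#' @return Interpolated percent contrast.
#' @export
contrast_at_variability <- function(curve, target_pct = 5) {
  cv <- curve[order(curve$filter_fwhm_mm), ]
  nv <- cv$variability_pct
  if (target_pct > max(nv) || target_pct < min(nv))
    stop(sprintf("target variability %.3g%% outside the measured span [%.3g, %.3g]%%: extrapolation refused",
                 target_pct, min(nv), max(nv)))
  exact <- which(nv == target_pct)
  if (length(exact)) return(cv$contrast_pct[exact[1]])
  # variability should decrease with filter width; find the bracketing pair
  for (i in seq_len(nrow(cv) - 1)) {
    a <- nv[i]; b <- nv[i + 1]
    if ((a - target_pct) * (b - target_pct) < 0) {
      f <- (target_pct - a) / (b - a)
      return(cv$contrast_pct[i] + f * (cv$contrast_pct[i + 1] - cv$contrast_pct[i]))
    }
  }
  stop("no bracketing filter widths for the target variability")
}

#' Contrast/variability curve over a Gaussian filter sweep
#'
#' @param image Normalized IQ [image_volume()].
#' @param sphere_centers,sphere_diameters,ratio,upsample See
#'   [nema_iq_analysis()].
#' @param filter_fwhms_mm Filter widths to sweep.
#' @return data.frame with one row per (filter, sphere).
#' @export
iq_filter_sweep <- function(image, sphere_centers, sphere_diameters,
                            ratio = 4, upsample = 10,
                            filter_fwhms_mm = 0:8) {
  res <- lapply(filter_fwhms_mm, function(f) {
    img <- gaussian_post_filter(image, f)
    r <- nema_iq_analysis(img, sphere_centers, sphere_diameters, ratio, upsample)
    r$filter_fwhm_mm <- f
    r
  })
  do.call(rbind, res)
}
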