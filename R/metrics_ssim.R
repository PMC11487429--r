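#' Structural similarity index of two 2D images
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, and a caller-supplied dynamic range (conventionally the
#' reference maximum). Local moments are computed by exact separable
#' Gaussian-window convolution with zero padding; the mean is taken over
#' the valid interior (margin of half the window) to avoid boundary bias.
#'
#' @param x,y Numeric matrices of equal size.
#' @param data_range Dynamic range `L`; defaults to `max(y)`.
#' @param window Window size (odd).
#' @param sigma Gaussian window sigma.
#' @param K1,K2 Stabilization constants.
#' @return Mean SSIM over the valid interior.
#' @export
ssim <- function(x, y, data_range = max(y), window = 11, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!all(dim(x) == dim(y))) stop("image dimensions differ")
  r <- (window - 1) / 2
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  conv2 <- function(m) t(sep_conv(t(sep_conv(m, k)), k))
  mx <- conv2(x); my <- conv2(y)
  mxx <- conv2(x * x); myy <- conv2(y * y); mxy <- conv2(x * y)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  interior <- s[(r + 1):(nrow(s) - r), (r + 1):(ncol(s) - r), drop = FALSE]
  mean(interior)
}

# zero-padded 1D convolution down the columns of m with centered kernel k
sep_conv <- function(m, k) {
  r <- (length(k) - 1) / 2
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (t in -r:r) {
    src <- (1 + max(0, -t)):(n - max(0, t))
    dst <- src + t
    out[dst, ] <- out[dst, ] + k[t + r + 1] * m[src, ]
  }
  out
}

#' SSIM versus Gaussian filter width
#'
#' Crops both images to the bounding box of the reference support, applies
#' each Gaussian filter to the reconstruction and reports SSIM per filter
#' width on the chosen transverse slice. When the reference has finer
#' slices than the reconstruction, the mean of the two nearest reference
#' slices is used.
#'
#' @param recon Reconstructed [image_volume()].
#' @param reference Ground-truth [image_volume()] (e.g. [voxelize()] of the
#'   activity phantom).
#' @param filter_fwhms_mm Filter widths to sweep.
#' @param slice Transverse (Z) slice index of the reconstruction; defaults
#'   to the middle slice.
#' @return data.frame: `filter_fwhm_mm`, `ssim`.
#' @export
ssim_curve <- function(recon, reference, filter_fwhms_mm = 0:8, slice = NULL) {
  g <- recon$grid
  if (is.null(slice)) slice <- ceiling(g$dim[3] / 2)
  zc <- grid_centers(g, 3)[slice]
  rz <- grid_centers(reference$grid, 3)
  ord <- order(abs(rz - zc))
  ref_slice <- if (reference$grid$voxel < g$voxel) {
    (reference$data[, , ord[1]] + reference$data[, , ord[2]]) / 2
  } else reference$data[, , ord[1]]
  # resample the reference in-plane onto the recon grid if needed
  if (!all(dim(ref_slice) == g$dim[1:2])) {
    rx <- grid_centers(reference$grid, 1); ry <- grid_centers(reference$grid, 2)
    xs <- grid_centers(g, 1); ys <- grid_centers(g, 2)
    ix <- vapply(xs, function(v) which.min(abs(rx - v)), 0L)
    iy <- vapply(ys, function(v) which.min(abs(ry - v)), 0L)
    ref_slice <- ref_slice[ix, iy]
  }
  # tight bounding box of the reference support
  sup <- which(ref_slice > 0, arr.ind = TRUE)
  if (!nrow(sup)) stop("reference slice has empty support")
  rr <- range(sup[, 1]); cc <- range(sup[, 2])
  ref_c <- ref_slice[rr[1]:rr[2], cc[1]:cc[2]]
  vapply(filter_fwhms_mm, function(f) {
    img <- gaussian_post_filter(recon, f)
    sl <- img$data[, , slice][rr[1]:rr[2], cc[1]:cc[2]]
    ssim(sl, ref_c, data_range = max(ref_c))
  }, 0) -> vals
  data.frame(filter_fwhm_mm = filter_fwhms_mm, ssim = vals)
}
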