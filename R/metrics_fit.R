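#' Fit a 3D Gaussian to a reconstructed source
#'
#' Nonlinear least squares of
#' `A * exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2) + (z-z0)^2/(2 sz^2))) + C`
#' against voxel values at voxel-center coordinates. Initialization: `A` =
#' max - min, center = centroid of the top-decile voxels, sigmas from
#' second moments, `C` = border median. Per-axis FWHM is
#' `2 sqrt(2 ln 2) * sigma`.
#'
#' @param image An [image_volume()] containing one dominant peak.
#' @param window Optional half-width (voxels) of a cube around the maximum
#'   (or around `center`) to restrict the fit to.
#' @param center Optional world coordinate (mm) of the expected peak; when
#'   given, the fit window is centered there instead of at the image
#'   maximum (robust when a noisy background carries the global maximum).
#' @param warn_multiple Warn if several local maxima exceed half the
#'   fitted amplitude (iterative reconstructions of point sources can
#'   develop multiple peaks).
#' @return A `gaussian_fit3d`: list with `A`, `center` (mm), `sigma` (mm),
#'   `C`, `fwhm` (mm), `converged`, `rss`.
#' @export
fit_gaussian_3d <- function(image, window = NULL, center = NULL,
                            warn_multiple = TRUE) {
  g <- image$grid
  arr <- image$data
  if (!is.null(window)) {
    w <- as.integer(window)
    pk <- if (is.null(center)) arrayInd(which.max(arr), dim(arr))
          else pmin(pmax(as.integer(ceiling((center - g$origin) / g$voxel)), 1L),
                    g$dim)
    lo <- pmax(pk - w, 1L)
    hi <- pmin(pk + w, g$dim)
    arr <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub <- image_grid(g$voxel, dim(arr), g$origin + (lo - 1L) * g$voxel)
    g <- sub
  }
  xs <- grid_centers(g, 1); ys <- grid_centers(g, 2); zs <- grid_centers(g, 3)
  co <- expand.grid(x = xs, y = ys, z = zs)
  v <- as.numeric(arr)
  # moment-based initialization
  C0 <- border_median(arr)
  A0 <- max(v) - min(v)
  thr <- stats::quantile(v, 0.9)
  top <- v >= thr
  wts <- pmax(v[top] - C0, 1e-12)
  ctr0 <- c(sum(co$x[top] * wts), sum(co$y[top] * wts), sum(co$z[top] * wts)) / sum(wts)
  sig0 <- sqrt(pmax(c(
    sum(wts * (co$x[top] - ctr0[1])^2),
    sum(wts * (co$y[top] - ctr0[2])^2),
    sum(wts * (co$z[top] - ctr0[3])^2)) / sum(wts), (g$voxel / 4)^2))
  df <- data.frame(v = v, x = co$x, y = co$y, z = co$z)
  ext <- (max(xs) - min(xs)) / 2
  try_fit <- function(start) {
    tryCatch(
      nls(v ~ A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2) +
                          (z - z0)^2 / (2 * sz^2))) + C,
          data = df, start = start, algorithm = "port",
          lower = c(A = 0, x0 = min(xs), y0 = min(ys), z0 = min(zs),
                    sx = g$voxel / 20, sy = g$voxel / 20, sz = g$voxel / 20,
                    C = -Inf),
          upper = c(A = Inf, x0 = max(xs), y0 = max(ys), z0 = max(zs),
                    sx = 2 * ext, sy = 2 * ext, sz = 2 * ext, C = Inf),
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
  }
  # multi-start: the moment initialization plus fixed-width peak-centered
  # starts (noisy backgrounds corrupt the moments; a point-like peak is
  # recovered from one of the narrow starts)
  pk_ctr <- if (!is.null(center)) center else ctr0
  starts <- c(list(list(A = A0, x0 = ctr0[1], y0 = ctr0[2], z0 = ctr0[3],
                        sx = sig0[1], sy = sig0[2], sz = sig0[3], C = C0)),
              lapply(c(1, 2.5, 6) * g$voxel, function(s0)
                list(A = A0, x0 = pk_ctr[1], y0 = pk_ctr[2], z0 = pk_ctr[3],
                     sx = s0, sy = s0, sz = s0, C = C0)))
  fits <- Filter(Negate(is.null), lapply(starts, try_fit))
  if (!length(fits)) {
    return(structure(list(A = NA, center = ctr0, sigma = sig0, C = C0,
                          fwhm = FWHM_SIGMA * sig0, converged = FALSE,
                          rss = NA), class = "gaussian_fit3d"))
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  fit <- fits[[which.min(rss)]]
  p <- coef(fit)
  sig <- abs(unname(p[c("sx", "sy", "sz")]))
  res <- structure(list(A = unname(p["A"]),
                        center = unname(p[c("x0", "y0", "z0")]),
                        sigma = sig, C = unname(p["C"]),
                        fwhm = FWHM_SIGMA * sig, converged = TRUE,
                        rss = sum(stats::resid(fit)^2)),
                   class = "gaussian_fit3d")
  if (warn_multiple && n_local_maxima(arr, res$C + res$A / 2) > 1)
    warning("multiple local maxima above half the fitted amplitude")
  res
}

#' @export
print.gaussian_fit3d <- function(x, ...) {
  cat(sprintf("<gaussian_fit3d: FWHM (%.2f, %.2f, %.2f) mm at (%.1f, %.1f, %.1f), A=%.3g, C=%.3g%s>\n",
              x$fwhm[1], x$fwhm[2], x$fwhm[3], x$center[1], x$center[2],
              x$center[3], x$A, x$C, if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

border_median <- function(arr) {
  d <- dim(arr)
  idx <- arrayInd(seq_along(arr), d)
  on_border <- idx[, 1] %in% c(1, d[1]) | idx[, 2] %in% c(1, d[2]) |
    idx[, 3] %in% c(1, d[3])
  median(arr[on_border])
}

n_local_maxima <- function(arr, threshold) {
  d <- dim(arr)
  cand <- which(arr > threshold)
  if (!length(cand)) return(0L)
  idx <- arrayInd(cand, d)
  cnt <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    v <- arr[i[1], i[2], i[3]]
    nb <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    ismax <- TRUE
    for (q in seq_len(nrow(nb))) {
      if (all(nb[q, ] == 0)) next
      j <- i + unlist(nb[q, ])
      if (any(j < 1) || any(j > d)) next
      if (arr[j[1], j[2], j[3]] > v) { ismax <- FALSE; break }
    }
    if (ismax) cnt <- cnt + 1L
  }
  cnt
}
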