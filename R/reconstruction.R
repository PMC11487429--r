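#' Exact radiological path of a LOR through a grid
#'
#' Siddon-style traversal: returns every voxel the segment crosses with its
#' exact intersection length; the lengths sum to the chord length of the
#' segment inside the grid.
#'
#' @param p1,p2 LOR endpoints (mm).
#' @param grid An [image_grid()].
#' @return data.frame with 1-based `i`, `j`, `k` voxel indices, `length`
#'   (mm) and `mid` (distance of the segment midpoint from `p1`, mm).
#' @export
ray_trace <- function(p1, p2, grid) {
  r <- cpp_ray_trace(as.numeric(p1), as.numeric(p2), grid$origin, grid$voxel,
                     grid$dim)
  f <- r$voxel
  nx <- grid$dim[1]; ny <- grid$dim[2]
  data.frame(i = f %% nx + 1L, j = (f %/% nx) %% ny + 1L,
             k = f %/% (nx * ny) + 1L, length = r$length, mid = r$mid)
}

#' TOF weights along a traversed LOR
#'
#' Gaussian weight in distance along the LOR between each voxel midpoint
#' and the TOF-most-likely point `L/2 + c * dt / 2` from the first
#' endpoint (`dt = t1 - t2`, so negative `dt` displaces the peak toward
#' endpoint 1). Truncated at 3 sigma.
#'
#' @param mid Midpoint distances from `p1` (mm), e.g. from [ray_trace()].
#' @param lor_length_mm Full endpoint-to-endpoint LOR length.
#' @param dt_ns Time difference `t1 - t2` in ns.
#' @param sigma_mm TOF sigma ([tof_sigma_mm()]); 0 disables TOF (all 1).
#' @return Weight vector.
#' @export
tof_weights <- function(mid, lor_length_mm, dt_ns, sigma_mm) {
  if (sigma_mm <= 0) return(rep(1, length(mid)))
  ctr <- lor_length_mm / 2 + C_MM_PER_NS * dt_ns / 2
  z <- (mid - ctr) / sigma_mm
  ifelse(abs(z) > 3, 0, exp(-z^2 / 2))
}

#' Monte Carlo sensitivity image
#'
#' Backprojects uniformly sampled admissible crystal pairs (different
#' panels, or sector difference within policy on the ring) to estimate the
#' per-voxel system-matrix column sum required by MLEM. Optionally smoothed
#' to suppress Monte Carlo noise.
#'
#' @param geometry A `scanner_geometry`.
#' @param grid An [image_grid()].
#' @param n_samples Number of sampled pairs.
#' @param min_sector_diff Ring acceptance (ignored for panels).
#' @param smooth_fwhm_mm Gaussian smoothing of the estimate (0 = none).
#' @return An [image_volume()].
#' @export
compute_sensitivity <- function(geometry, grid, n_samples = 2e6,
                                min_sector_diff = 4, smooth_fwhm_mm = 0) {
  stopifnot(n_samples > 0)
  ids <- seq_len(geometry$n_crystals)
  centers <- crystal_center(geometry, ids)
  grp <- panel_of(geometry, ids)
  basis <- crystal_basis(geometry, ids)
  mode <- if (geometry$type == "panel") 0L else 1L
  ngr <- if (geometry$type == "panel") geometry$n_panels else geometry$n_sectors
  s <- cpp_sensitivity(centers, as.integer(grp), basis$u, basis$v,
                       geometry$crystal$cross_section / 2, mode, ngr,
                       as.integer(min_sector_diff), n_samples,
                       grid$origin, grid$voxel, grid$dim)
  if (smooth_fwhm_mm > 0)
    s <- cpp_gauss_filter3(s, grid$dim, smooth_fwhm_mm / FWHM_SIGMA / grid$voxel)
  image_volume(array(s, grid$dim), grid)
}

# in-plane basis vectors of each crystal face (transverse aperture)
crystal_basis <- function(geometry, id) {
  if (geometry$type == "panel") {
    h <- panel_hier(geometry, id)
    list(u = geometry$uaxis[h$panel, , drop = FALSE],
         v = matrix(c(0, 0, 1), length(id), 3, byrow = TRUE))
  } else {
    h <- ring_hier(geometry, id)
    phi <- (h$kt - 0.5) * geometry$dphi
    list(u = cbind(-sin(phi), cos(phi), 0),
         v = matrix(c(0, 0, 1), length(id), 3, byrow = TRUE))
  }
}

# LOR endpoints: crystal-volume centers at depth length/2, with `k` rays
# per event sampling the transverse crystal aperture uniformly (k = 0
# gives the bare center ray, which aliases badly when the voxel size is
# much smaller than the crystal pitch).
lor_endpoints <- function(geometry, listmode, k = 0) {
  e1 <- crystal_center(geometry, listmode$id1)
  e2 <- crystal_center(geometry, listmode$id2)
  if (k > 0) {
    cs <- geometry$crystal$cross_section
    rep_rows <- rep(seq_len(nrow(e1)), each = k)
    e1 <- e1[rep_rows, , drop = FALSE]
    e2 <- e2[rep_rows, , drop = FALSE]
    b1 <- crystal_basis(geometry, listmode$id1[rep_rows])
    b2 <- crystal_basis(geometry, listmode$id2[rep_rows])
    n <- nrow(e1)
    # stratified over an m x m sub-grid when k is a perfect square
    m <- as.integer(round(sqrt(k)))
    jit <- function() {
      if (m * m == k) {
        su <- rep_len(rep(seq_len(m) - 1L, each = m), n)
        sv <- rep_len(rep(seq_len(m) - 1L, times = m), n)
        list(u = ((su + runif(n)) / m - 0.5) * cs,
             v = ((sv + runif(n)) / m - 0.5) * cs)
      } else {
        list(u = runif(n, -cs / 2, cs / 2), v = runif(n, -cs / 2, cs / 2))
      }
    }
    j1 <- jit()
    j2 <- jit()
    if (m * m == k && k > 1) {  # decorrelate the two endpoints' strata
      perm <- rep(c(seq(2L, k), 1L), length.out = n) +
        rep(seq(0L, n - 1L, by = k), each = k)
      j2 <- list(u = j2$u[perm], v = j2$v[perm])
    }
    e1 <- e1 + j1$u * b1$u + j1$v * b1$v
    e2 <- e2 + j2$u * b2$u + j2$v * b2$v
  }
  list(e1 = e1, e2 = e2)
}

#' List-mode TOF-MLEM reconstruction
#'
#' Standard multiplicative list-mode MLEM,
#' `x_j <- (x_j / s_j) * sum_i a_ij / sum_k a_ik x_k`, with the system
#' matrix given by Siddon intersection lengths, optionally weighted by a
#' Gaussian TOF kernel. Initialization is uniform inside the sensitivity
#' support; non-negativity is preserved by construction.
#'
#' @param listmode Coincidence table with `id1`, `id2`, `dt_ns` (see
#'   [process_acquisition()]).
#' @param geometry A `scanner_geometry` (for the LOR endpoints).
#' @param grid An [image_grid()].
#' @param n_iter Number of full MLEM iterations.
#' @param tof Logical: apply the TOF kernel.
#' @param ctr_ps CTR defining the kernel width.
#' @param sensitivity Sensitivity [image_volume()] from
#'   [compute_sensitivity()] (computed on the fly when `NULL`).
#' @param aperture_rays Number of rays per event sampling the transverse
#'   crystal aperture; the event's system-matrix row is their average, so
#'   the detector footprint is modelled in the projector (a desk-scale
#'   stand-in for a distance-driven projector). 0 uses the bare
#'   center-to-center ray, which aliases when voxels are much smaller than
#'   the crystal pitch.
#' @param ... Passed to [compute_sensitivity()] when it is computed here.
#' @return Reconstructed [image_volume()].
#' @export
mlem <- function(listmode, geometry, grid, n_iter = 30, tof = TRUE,
                 ctr_ps = 75, sensitivity = NULL, aperture_rays = 4, ...) {
  if (nrow(listmode) == 0) stop("empty list-mode data")
  if (is.null(sensitivity))
    sensitivity <- compute_sensitivity(geometry, grid, ...)
  stopifnot(all(sensitivity$grid$dim == grid$dim))
  if (all(sensitivity$data <= 0)) stop("all-zero sensitivity image")
  ep <- lor_endpoints(geometry, listmode, k = aperture_rays)
  sig <- if (tof) tof_sigma_mm(ctr_ps) else 0
  x <- cpp_mlem(ep$e1, ep$e2, listmode$dt_ns, grid$origin, grid$voxel,
                grid$dim, as.integer(n_iter), sig,
                as.numeric(sensitivity$data), max(1L, as.integer(aperture_rays)))
  image_volume(array(x, grid$dim), grid)
}

#' Gaussian post-filter
#'
#' Isotropic Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`,
#' normalized kernel (total intensity preserved for interior support),
#' zero-padded boundaries.
#'
#' @param image An [image_volume()].
#' @param fwhm_mm Filter FWHM in mm; 0 returns the input unchanged.
#' @return Filtered [image_volume()].
#' @export
gaussian_post_filter <- function(image, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(image)
  g <- image$grid
  out <- cpp_gauss_filter3(as.numeric(image$data), g$dim,
                           fwhm_mm / FWHM_SIGMA / g$voxel)
  image_volume(array(out, g$dim), g)
}

# matrix-free forward/backward projection (small-instance property tests)
forward_project <- function(x, e1, e2, dt_ns, grid, sigma_tof = 0)
  cpp_forward_project(as.numeric(x), rbind(e1), rbind(e2), dt_ns,
                      grid$origin, grid$voxel, grid$dim, sigma_tof)

back_project <- function(y, e1, e2, dt_ns, grid, sigma_tof = 0)
  array(cpp_back_project(y, rbind(e1), rbind(e2), dt_ns,
                         grid$origin, grid$voxel, grid$dim, sigma_tof),
        grid$dim)
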