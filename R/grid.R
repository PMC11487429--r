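#' Image grid
#'
#' Regular isotropic voxel grid in world coordinates. `origin` is the
#' minimum corner of the grid; the center of voxel `(i, j, k)` (1-based)
#' is at `origin + (index - 0.5) * voxel`. Axis order is fixed at
#' (X, Y, Z = axial).
#'
#' @param voxel_mm Isotropic voxel size (mm).
#' @param dim Integer 3-vector of voxel counts.
#' @param origin Minimum-corner world coordinate (mm).
#' @return An `image_grid`.
#' @export
image_grid <- function(voxel_mm, dim, origin) {
  stopifnot(voxel_mm > 0, length(dim) == 3, all(dim >= 1), length(origin) == 3)
  structure(list(voxel = voxel_mm, dim = as.integer(dim),
                 origin = as.numeric(origin)), class = "image_grid")
}

#' @rdname image_grid
#' @param center World coordinate of the grid center (mm).
#' @export
image_grid_centered <- function(voxel_mm, dim, center = c(0, 0, 0)) {
  if (length(dim) == 1) dim <- rep(dim, 3)
  image_grid(voxel_mm, dim, center - dim * voxel_mm / 2)
}

#' Voxel center coordinates along one axis
#' @param grid An `image_grid`.
#' @param axis 1, 2 or 3.
#' @export
grid_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 0.5) * grid$voxel
}

#' Image volume
#'
#' A 3D array of voxel values bound to its [image_grid()].
#'
#' @param data 3D numeric array matching `grid$dim`.
#' @param grid An `image_grid`.
#' @export
image_volume <- function(data, grid) {
  stopifnot(inherits(grid, "image_grid"), all(dim(data) == grid$dim))
  structure(list(data = data, grid = grid), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<image_volume %dx%dx%d @ %.2f mm, range [%.3g, %.3g]>\n",
              g$dim[1], g$dim[2], g$dim[3], g$voxel,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Write / read an image volume (raw float32 + JSON sidecar)
#'
#' Voxel data is stored little-endian float32 in Fortran (column-major)
#' order; the sidecar records dimensions, voxel size and origin.
#'
#' @param img An `image_volume`.
#' @param path Output path for the `.f32` file; the sidecar gets `.json`
#'   appended.
#' @export
write_image <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(img$data), con, size = 4, endian = "little")
  jsonlite::write_json(list(dim = img$grid$dim, voxel_mm = img$grid$voxel,
                            origin_mm = img$grid$origin, dtype = "float32",
                            order = "F"),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  image_volume(array(v, meta$dim), image_grid(meta$voxel_mm, meta$dim, meta$origin_mm))
}
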