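#' Geometric phantom primitives
#'
#' Building blocks for analytic activity/attenuation phantoms. Each
#' primitive carries an activity concentration (kBq/mL) and a material tag
#' used by the photon transport. In a phantom, later primitives override
#' earlier ones wherever they overlap (both activity and material).
#'
#' @param center 3-vector, mm.
#' @param radius_mm,length_mm,size_mm Dimensions, mm. `size_mm` is the full
#'   box edge length (scalar or 3-vector).
#' @param axis Cylinder axis (unit vector, normalized internally).
#' @param activity_kBq_mL Activity concentration, kBq/mL.
#' @param material One of `"air"`, `"water"`, `"polyethylene"`, `"lung"`.
#' @return A `phantom_primitive`.
#' @name primitives
NULL

new_primitive <- function(shape, center, dims, axis, activity, material) {
  ndim <- switch(shape, sphere = 1, cylinder = 2, box = 3)
  stopifnot(all(dims[seq_len(ndim)] > 0), activity >= 0)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(shape = shape, center = as.numeric(center), dims = dims,
                 axis = axis, activity = activity, material = material,
                 mat_idx = material_index(material)),
            class = "phantom_primitive")
}

#' @rdname primitives
#' @export
prim_sphere <- function(center, radius_mm, activity_kBq_mL = 0, material = "water")
  new_primitive("sphere", center, c(radius_mm, 0, 0), c(0, 0, 1),
                activity_kBq_mL, material)

#' @rdname primitives
#' @export
prim_cylinder <- function(center, radius_mm, length_mm, axis = c(0, 0, 1),
                          activity_kBq_mL = 0, material = "water")
  new_primitive("cylinder", center, c(radius_mm, length_mm / 2, 0), axis,
                activity_kBq_mL, material)

#' @rdname primitives
#' @export
prim_box <- function(center, size_mm, activity_kBq_mL = 0, material = "water") {
  if (length(size_mm) == 1) size_mm <- rep(size_mm, 3)
  new_primitive("box", center, size_mm / 2, c(0, 0, 1), activity_kBq_mL, material)
}

primitive_volume_mm3 <- function(p) {
  switch(p$shape,
         sphere = 4 / 3 * pi * p$dims[1]^3,
         cylinder = pi * p$dims[1]^2 * (2 * p$dims[2]),
         box = prod(2 * p$dims))
}

#' Analytic phantom
#'
#' An ordered sequence of primitives over a homogeneous background
#' material. Later primitives override earlier ones in overlapping
#' regions, so e.g. zero-activity inserts can be punched into an active
#' background.
#'
#' @param primitives List of [primitives].
#' @param background Background material name (default `"air"`).
#' @return An `analytic_phantom`.
#' @export
analytic_phantom <- function(primitives, background = "air") {
  stopifnot(length(primitives) >= 1,
            all(vapply(primitives, inherits, TRUE, "phantom_primitive")))
  structure(list(primitives = primitives, background = background,
                 bg_idx = material_index(background)),
            class = "analytic_phantom")
}

#' @export
print.analytic_phantom <- function(x, ...) {
  cat(sprintf("<analytic_phantom: %d primitives on %s, total activity %.3g kBq>\n",
              length(x$primitives), x$background, phantom_activity(x) / 1e3))
  invisible(x)
}

# numeric encoding consumed by the C++ transport/voxelizer:
# type(1 sph,2 cyl,3 box), cx,cy,cz, d1,d2,d3, ax,ay,az, conc, mat_idx
phantom_matrix <- function(phantom) {
  t(vapply(phantom$primitives, function(p) {
    c(switch(p$shape, sphere = 1, cylinder = 2, box = 3),
      p$center, p$dims, p$axis, p$activity, p$mat_idx)
  }, numeric(12)))
}

phantom_bound_radius <- function(phantom) {
  r <- vapply(phantom$primitives, function(p) {
    ext <- switch(p$shape,
                  sphere = p$dims[1],
                  cylinder = sqrt(p$dims[1]^2 + p$dims[2]^2),
                  box = sqrt(sum(p$dims^2)))
    sqrt(sum(p$center^2)) + ext
  }, 0)
  max(r) + 1
}

point_in_primitive <- function(p, points) {
  points <- rbind(points)
  w <- points - matrix(p$center, nrow(points), 3, byrow = TRUE)
  switch(p$shape,
         sphere = rowSums(w^2) <= p$dims[1]^2,
         cylinder = {
           h <- w %*% p$axis
           r2 <- rowSums(w^2) - h^2
           abs(h) <= p$dims[2] & r2 <= p$dims[1]^2
         },
         box = abs(w[, 1]) <= p$dims[1] & abs(w[, 2]) <= p$dims[2] &
           abs(w[, 3]) <= p$dims[3])
}

#' Total phantom activity
#'
#' Sum of concentration x net volume with overlap resolved by override
#' order. Net volumes of overlapped primitives are estimated by Monte
#' Carlo; phantoms without overlap are summed in closed form.
#'
#' @param phantom An `analytic_phantom`.
#' @param n_mc Monte Carlo points per overlapped primitive.
#' @return Total activity in Bq.
#' @export
phantom_activity <- function(phantom, n_mc = 20000) {
  prims <- phantom$primitives
  k <- length(prims)
  tot <- 0
  for (i in seq_len(k)) {
    p <- prims[[i]]
    if (p$activity == 0) next
    v <- primitive_volume_mm3(p)
    if (i < k) {
      # fraction not covered by any later (overriding) primitive
      pts <- sample_in_primitive(p, n_mc)
      cov <- rep(FALSE, n_mc)
      for (j in seq((i + 1), k))
        cov <- cov | point_in_primitive(prims[[j]], pts)
      v <- v * (1 - mean(cov))
    }
    tot <- tot + p$activity * v   # kBq/mL * mm^3 = Bq
  }
  tot
}

sample_in_primitive <- function(p, n) {
  if (n == 0) return(matrix(0, 0, 3))
  pts <- switch(p$shape,
    sphere = {
      r <- p$dims[1] * runif(n)^(1 / 3)
      z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
      s <- sqrt(1 - z^2)
      cbind(r * s * cos(phi), r * s * sin(phi), r * z)
    },
    cylinder = {
      r <- p$dims[1] * sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
      h <- runif(n, -p$dims[2], p$dims[2])
      # local frame with e3 = axis
      e3 <- p$axis
      e1 <- if (abs(e3[3]) < 0.9) c(-e3[2], e3[1], 0) else c(1, 0, 0)
      e1 <- e1 - sum(e1 * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
              e3[3] * e1[1] - e3[1] * e1[3],
              e3[1] * e1[2] - e3[2] * e1[1])
      outer(r * cos(phi), e1) + outer(r * sin(phi), e2) + outer(h, e3)
    },
    box = cbind(runif(n, -p$dims[1], p$dims[1]),
                runif(n, -p$dims[2], p$dims[2]),
                runif(n, -p$dims[3], p$dims[3])))
  pts + matrix(p$center, n, 3, byrow = TRUE)
}

#' Sample annihilation emission points
#'
#' Points are drawn with probability proportional to the local activity
#' concentration: a primitive is selected with probability proportional to
#' concentration x gross volume, a point is drawn uniformly inside it, and
#' draws falling inside a later (overriding) primitive are rejected and
#' redrawn, which yields the exact net-activity distribution.
#'
#' @param phantom An `analytic_phantom` with positive total activity.
#' @param n Number of points.
#' @return n x 3 matrix of emission points (mm).
#' @export
sample_emission <- function(phantom, n) {
  prims <- phantom$primitives
  w <- vapply(prims, function(p) p$activity * primitive_volume_mm3(p), 0)
  if (sum(w) <= 0) stop("phantom has zero total activity")
  cpp_sample_emission(as.integer(n), phantom_matrix(phantom), cumsum(w))
}

#' Voxelize a phantom onto an image grid
#'
#' Per-voxel mean activity concentration via supersampling; serves as the
#' SSIM reference and as a sanity oracle for reconstructions.
#'
#' @param phantom An `analytic_phantom`.
#' @param grid An [image_grid()].
#' @param supersample Sample points per voxel edge.
#' @return An [image_volume()] of concentrations (kBq/mL).
#' @export
voxelize <- function(phantom, grid, supersample = 3) {
  arr <- cpp_voxelize(phantom_matrix(phantom), grid$origin, grid$voxel,
                      as.integer(grid$dim), as.integer(supersample))
  image_volume(array(arr, grid$dim), grid)
}

# ---- phantom library ----------------------------------------------------

#' NEMA NU 2-2018 image-quality body phantom
#'
#' Torso-shaped water background (two half-cylinders joined by a box,
#' interior ~9.8 L), six hot spheres (inner diameters 10--37 mm) on a
#' 57.2 mm radius ring in the central slice, and a central low-density
#' zero-activity lung insert. All six spheres are hot with the same
#' concentration (sphere:background = 4 at the defaults).
#'
#' @param background_kBq_mL Background concentration.
#' @param sphere_kBq_mL Sphere concentration.
#' @return An `analytic_phantom`; attributes `sphere_centers` and
#'   `sphere_diameters` carry the layout for the IQ analysis.
#' @export
nema_iq_phantom <- function(background_kBq_mL = 5.3, sphere_kBq_mL = 21.25) {
  stopifnot(background_kBq_mL >= 0, sphere_kBq_mL >= 0)
  len <- 180
  prims <- list(
    prim_cylinder(c(-36.5, 0, 0), 110.5, len, activity_kBq_mL = background_kBq_mL),
    prim_cylinder(c(36.5, 0, 0), 110.5, len, activity_kBq_mL = background_kBq_mL),
    prim_box(c(0, 0, 0), c(73, 221, len), activity_kBq_mL = background_kBq_mL),
    prim_cylinder(c(0, 0, 0), 25, len, activity_kBq_mL = 0, material = "lung")
  )
  d <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(d) - 1) * pi / 3
  centers <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)
  for (i in seq_along(d))
    prims <- c(prims, list(prim_sphere(centers[i, ], d[i] / 2,
                                       activity_kBq_mL = sphere_kBq_mL)))
  ph <- analytic_phantom(prims, background = "air")
  attr(ph, "sphere_centers") <- centers
  attr(ph, "sphere_diameters") <- d
  attr(ph, "ratio") <- if (background_kBq_mL > 0) sphere_kBq_mL / background_kBq_mL else Inf
  ph
}

point_source_primitive <- function(center, radius_mm = 0.1, activity_Bq = 70) {
  conc <- activity_Bq / (4 / 3 * pi * radius_mm^3)  # Bq/mm^3 = kBq/mL
  prim_sphere(center, radius_mm, activity_kBq_mL = conc, material = "water")
}

#' Grid of point sources for the resolution study
#'
#' 0.1 mm radius spherical sources on an `n_per_axis`^3 cubic grid with one
#' corner at the FOV center, filling the first octant. Each source is its
#' own single-primitive phantom in air (they are simulated separately).
#'
#' @param n_per_axis Sources per axis.
#' @param spacing_mm Grid spacing.
#' @param radius_mm Source radius.
#' @param activity_Bq Source activity.
#' @return List of `analytic_phantom`s; attribute `positions` holds the
#'   source centers.
#' @export
point_source_grid <- function(n_per_axis = 5, spacing_mm = 37, radius_mm = 0.1,
                              activity_Bq = 70) {
  idx <- expand.grid(i = 0:(n_per_axis - 1), j = 0:(n_per_axis - 1),
                     k = 0:(n_per_axis - 1))
  pos <- as.matrix(idx) * spacing_mm
  phs <- lapply(seq_len(nrow(pos)), function(r)
    analytic_phantom(list(point_source_primitive(pos[r, ], radius_mm, activity_Bq)),
                     background = "air"))
  attr(phs, "positions") <- unname(pos)
  phs
}

#' Point source inside a homogeneous background cube
#'
#' The variant used to suppress edge artifacts of the non-negativity
#' constraint at higher iteration counts: a 0.1 mm source overriding a
#' 4 cm water cube of low activity centered on the source, giving an
#' image-domain signal-to-background ratio of about 8.
#'
#' @param source_center 3-vector, mm.
#' @param bg_side_mm Cube side.
#' @param bg_activity_kBq Total cube activity (28.8 kBq over 64 mL =
#'   0.45 kBq/mL).
#' @param source_activity_Bq Source activity.
#' @return An `analytic_phantom`.
#' @export
point_source_with_background <- function(source_center = c(0, 0, 0),
                                         bg_side_mm = 40,
                                         bg_activity_kBq = 28.8,
                                         source_activity_Bq = 70) {
  conc <- bg_activity_kBq * 1e3 / bg_side_mm^3  # Bq/mm^3 = kBq/mL
  prims <- list()
  if (bg_activity_kBq > 0)
    prims <- list(prim_box(source_center, bg_side_mm, activity_kBq_mL = conc))
  prims <- c(prims, list(point_source_primitive(source_center,
                                                activity_Bq = source_activity_Bq)))
  analytic_phantom(prims, background = "air")
}

#' Homogeneous normalization cube
#'
#' A 36 cm activity cube in air filling the reconstructed FOV, used to
#' build the post-hoc normalization correction for the image-quality
#' analysis.
#'
#' @param side_mm Cube side.
#' @param activity_kBq_mL Concentration.
#' @return An `analytic_phantom`.
#' @export
normalization_cube <- function(side_mm = 360, activity_kBq_mL = 1) {
  analytic_phantom(list(prim_box(c(0, 0, 0), side_mm,
                                 activity_kBq_mL = activity_kBq_mL,
                                 material = "air")),
                   background = "air")
}

#' NECR count-rate phantom
#'
#' 70 cm long, 10 cm radius polyethylene cylinder with a full-length
#' 1.6 mm radius line source offset 45 mm from the axis (NEMA NU 2
#' convention). `activity_kBq_mL` is the NEMA activity concentration:
#' total line activity divided by the phantom volume (22 L).
#'
#' @param activity_kBq_mL Activity per phantom volume.
#' @param radius_mm,length_mm,line_radius_mm Phantom dimensions.
#' @return An `analytic_phantom`.
#' @export
necr_phantom <- function(activity_kBq_mL = 10, radius_mm = 100, length_mm = 700,
                         line_radius_mm = 1.6) {
  stopifnot(activity_kBq_mL >= 0)
  vol_phantom <- pi * radius_mm^2 * length_mm / 1e3       # mL
  total_kBq <- activity_kBq_mL * vol_phantom
  vol_line <- pi * line_radius_mm^2 * length_mm / 1e3     # mL
  prims <- list(
    prim_cylinder(c(0, 0, 0), radius_mm, length_mm, activity_kBq_mL = 0,
                  material = "polyethylene"),
    prim_cylinder(c(0, -45, 0), line_radius_mm, length_mm,
                  activity_kBq_mL = total_kBq / vol_line, material = "polyethylene")
  )
  ph <- analytic_phantom(prims, background = "air")
  attr(ph, "total_kBq") <- total_kBq
  ph
}

#' Procedural hot-rod (Derenzo-style) phantom
#'
#' Stand-in for anatomical phantoms in qualitative/SSIM studies: six
#' 60-degree sectors of hot rods in a cold water cylinder, one rod
#' diameter per sector, center-to-center spacing twice the diameter,
#' triangular packing.
#'
#' @param rod_diameters_mm Six rod diameters.
#' @param activity_kBq_mL Rod concentration.
#' @param disc_radius_mm Cylinder radius.
#' @param length_mm Axial extent.
#' @return An `analytic_phantom`.
#' @export
derenzo_phantom <- function(rod_diameters_mm = c(2, 2.5, 3, 4, 5, 6),
                            activity_kBq_mL = 10, disc_radius_mm = 50,
                            length_mm = 20) {
  stopifnot(length(rod_diameters_mm) == 6)
  prims <- list(prim_cylinder(c(0, 0, 0), disc_radius_mm, length_mm,
                              activity_kBq_mL = 0, material = "water"))
  margin <- 6
  for (s in 0:5) {
    d <- rod_diameters_mm[s + 1]
    sp <- 2 * d
    theta <- s * pi / 3 + pi / 6    # sector bisector
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    row <- 0
    repeat {
      y <- margin + row * sp * sqrt(3) / 2
      if (y + d / 2 > disc_radius_mm - margin) break
      xs <- (seq_len(row + 1) - 1 - row / 2) * sp
      for (x in xs) {
        # keep the rod inside its 60-degree wedge and the disc
        ang <- atan2(x, y)
        if (abs(ang) > pi / 6 - d / (2 * y + 1e-9)) next
        if (sqrt(x^2 + y^2) + d / 2 > disc_radius_mm - margin) next
        p <- rot %*% c(x, y)
        prims <- c(prims, list(prim_cylinder(c(p[1], p[2], 0), d / 2, length_mm,
                                             activity_kBq_mL = activity_kBq_mL)))
      }
      row <- row + 1
    }
  }
  if (length(prims) < 7) stop("rod layout does not fit in the disc")
  analytic_phantom(prims, background = "air")
}
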