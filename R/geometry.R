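#' Crystal specification
#'
#' Square-cross-section scintillator crystal. The pitch is the
#' center-to-center spacing on the detector grid; a cross-section smaller
#' than the pitch yields a sparse configuration with vacuum gaps.
#'
#' @param cross_section_mm Side of the square cross-section (mm).
#' @param length_mm Crystal depth along the photon incidence direction (mm).
#' @param pitch_mm Center-to-center spacing (mm); defaults to the
#'   cross-section (gap-free packing).
#' @return A `crystal_spec` object.
#' @examples
#' crystal_spec(3, 10)          # 3 x 3 x 10 mm LYSO, full packing
#' crystal_spec(1.5, 10, 2)     # sparse: 1.5 mm crystals on a 2 mm grid
#' @export
crystal_spec <- function(cross_section_mm, length_mm, pitch_mm = cross_section_mm) {
  stopifnot(cross_section_mm > 0, length_mm > 0,
            cross_section_mm <= pitch_mm)
  structure(list(cross_section = cross_section_mm, length = length_mm,
                 pitch = pitch_mm), class = "crystal_spec")
}

#' Build a flat-panel scanner geometry
#'
#' Four (by default) square detector panels around the axial (Z) axis,
#' facing each other at `separation_mm` measured between the inner crystal
#' faces. Panels 1 and 2 sit on +X/-X, panels 3 and 4 on +Y/-Y. Crystals
#' are indexed panel-major, then axial-row-major, then column; the flat
#' index is 1-based.
#'
#' @param crystal A [crystal_spec()].
#' @param n_panels Number of panels (1, 2 or 4; opposing pairs).
#' @param separation_mm Inner-face to inner-face distance (mm).
#' @param panel_extent_mm Panel side (mm); must be divisible by the pitch.
#' @return A `scanner_geometry` object.
#' @examples
#' g <- build_flat_panel(crystal_spec(3, 10))
#' g$n_crystals                     # 40,000
#' total_crystal_volume(g)          # 3.6 dm^3
#' @export
build_flat_panel <- function(crystal, n_panels = 4, separation_mm = 400,
                             panel_extent_mm = 300) {
  stopifnot(inherits(crystal, "crystal_spec"), n_panels %in% c(1, 2, 4))
  n_side <- panel_extent_mm / crystal$pitch
  if (abs(n_side - round(n_side)) > 1e-9)
    stop("panel extent (", panel_extent_mm, " mm) is not divisible by the pitch (",
         crystal$pitch, " mm)")
  n_side <- as.integer(round(n_side))
  # panel frames: face center, inward normal, u (transaxial), v (axial = Z)
  normals <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0))
  faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)) * separation_mm / 2
  us <- rbind(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0), c(1, 0, 0))
  structure(list(
    type = "panel", crystal = crystal,
    n_panels = n_panels, separation = separation_mm, extent = panel_extent_mm,
    n_side = n_side, per_panel = n_side^2,
    n_crystals = n_panels * n_side^2,
    face = faces[seq_len(n_panels), , drop = FALSE],
    normal = normals[seq_len(n_panels), , drop = FALSE],
    uaxis = us[seq_len(n_panels), , drop = FALSE],
    submodule = 5L,
    axial_extent = panel_extent_mm
  ), class = "scanner_geometry")
}

#' Build the reference cylindrical scanner geometry
#'
#' A 19-sector ring modelled on a modern clinical TOF-PET scanner:
#' 3.2 x 3.2 x 20 mm LSO crystals grouped into 5 x 5 submodules, 4 x 2
#' submodules per module (transaxial x axial), 2 x 8 modules per sector,
#' giving 760 transaxial x 80 axial = 60,800 crystals on a 78 cm bore with
#' a 26.3 cm axial FOV. Sectors are spaced uniformly with crystals placed
#' as flat boxes at the sector-local tangential grid.
#'
#' @param bore_mm Bore diameter (mm); crystals start at `bore_mm / 2`.
#' @param axial_fov_mm Axial field of view (mm).
#' @param crystal A [crystal_spec()]; the axial/tangential pitch follows
#'   from the crystal counts and the bore/axial extents.
#' @param n_sectors Number of sectors in the ring.
#' @return A `scanner_geometry` object.
#' @examples
#' r <- build_reference_ring()
#' r$n_crystals                    # 60,800
#' round(total_crystal_volume(r), 2) # 12.45 dm^3
#' @export
build_reference_ring <- function(bore_mm = 780, axial_fov_mm = 263,
                                 crystal = crystal_spec(3.2, 20),
                                 n_sectors = 19L) {
  nt_sector <- 2L * 4L * 5L      # modules x submodules x crystals, transaxial
  na <- 8L * 2L * 5L             # axial
  nt <- n_sectors * nt_sector
  structure(list(
    type = "ring", crystal = crystal,
    n_sectors = as.integer(n_sectors), nt = nt, na = na,
    nt_sector = nt_sector,
    n_crystals = nt * na,
    r_inner = bore_mm / 2,
    axial_fov = axial_fov_mm,
    axial_pitch = axial_fov_mm / na,
    dphi = 2 * pi / nt,
    submodule = 5L,
    axial_extent = axial_fov_mm
  ), class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cs <- x$crystal
  cat(sprintf("<scanner_geometry: %s, %d crystals, %.1fx%.1fx%.1f mm (pitch %.1f), %.2f dm^3>\n",
              x$type, x$n_crystals, cs$cross_section, cs$cross_section,
              cs$length, cs$pitch, total_crystal_volume(x)))
  invisible(x)
}

#' Total scintillator volume of a geometry
#'
#' @param geometry A `scanner_geometry`.
#' @return Volume in dm^3 (`n_crystals * cross_section^2 * length`).
#' @export
total_crystal_volume <- function(geometry) {
  cs <- geometry$crystal
  geometry$n_crystals * cs$cross_section^2 * cs$length / 1e6
}

# hierarchical decomposition of 1-based flat ids
panel_hier <- function(geometry, id) {
  stopifnot(all(id >= 1), all(id <= geometry$n_crystals))
  id0 <- id - 1L
  per <- geometry$per_panel
  panel <- id0 %/% per
  rest <- id0 %% per
  list(panel = panel + 1L,
       row = rest %/% geometry$n_side + 1L,   # axial (v/Z) index
       col = rest %% geometry$n_side + 1L)    # transaxial (u) index
}

ring_hier <- function(geometry, id) {
  stopifnot(all(id >= 1), all(id <= geometry$n_crystals))
  id0 <- id - 1L
  kt <- id0 %/% geometry$na      # 0-based transaxial index
  ka <- id0 %% geometry$na       # 0-based axial index
  list(kt = kt + 1L, ka = ka + 1L,
       sector = kt %/% geometry$nt_sector + 1L)
}

#' Crystal center in world coordinates
#'
#' Returns the geometric center of the crystal volume, which is also the
#' LOR endpoint used by the reconstruction (half the crystal length behind
#' the entrance face; no depth-of-interaction measurement is simulated, so
#' parallax error emerges naturally).
#'
#' @param geometry A `scanner_geometry`.
#' @param id Vector of 1-based flat crystal indices.
#' @return Numeric matrix `length(id)` x 3 of world coordinates (mm).
#' @export
crystal_center <- function(geometry, id) {
  if (geometry$type == "panel") {
    h <- panel_hier(geometry, id)
    half <- geometry$extent / 2
    p <- geometry$crystal$pitch
    u <- -half + (h$col - 0.5) * p
    v <- -half + (h$row - 0.5) * p
    depth <- geometry$crystal$length / 2
    face <- geometry$face[h$panel, , drop = FALSE]
    nrm <- geometry$normal[h$panel, , drop = FALSE]
    ua <- geometry$uaxis[h$panel, , drop = FALSE]
    va <- matrix(c(0, 0, 1), nrow = length(id), ncol = 3, byrow = TRUE)
    face - depth * nrm + u * ua + v * va
  } else {
    h <- ring_hier(geometry, id)
    phi <- (h$kt - 0.5) * geometry$dphi
    rc <- geometry$r_inner + geometry$crystal$length / 2
    z <- -geometry$axial_fov / 2 + (h$ka - 0.5) * geometry$axial_pitch
    cbind(rc * cos(phi), rc * sin(phi), z)
  }
}

#' Locate the crystal containing a world point
#'
#' Inverse of [crystal_center()] for points inside a crystal volume.
#'
#' @param geometry A `scanner_geometry`.
#' @param points Numeric matrix n x 3 (mm).
#' @return Integer vector of flat crystal ids; `NA` for points in gaps or
#'   outside the detector.
#' @export
locate_crystal <- function(geometry, points) {
  points <- rbind(points)
  if (geometry$type == "panel") {
    out <- rep(NA_integer_, nrow(points))
    cs <- geometry$crystal
    half <- geometry$extent / 2
    for (p in seq_len(geometry$n_panels)) {
      nrm <- geometry$normal[p, ]
      face <- geometry$face[p, ]
      ua <- geometry$uaxis[p, ]
      d <- (points - matrix(face, nrow(points), 3, byrow = TRUE)) %*% (-nrm)
      u <- points %*% ua
      v <- points[, 3]
      inside_slab <- d >= 0 & d <= cs$length & abs(u) <= half & abs(v) <= half
      col <- pmin(pmax(floor((u + half) / cs$pitch), 0), geometry$n_side - 1)
      row <- pmin(pmax(floor((v + half) / cs$pitch), 0), geometry$n_side - 1)
      uc <- -half + (col + 0.5) * cs$pitch
      vc <- -half + (row + 0.5) * cs$pitch
      in_cry <- inside_slab & abs(u - uc) <= cs$cross_section / 2 &
        abs(v - vc) <= cs$cross_section / 2
      hit <- which(in_cry & is.na(out))
      out[hit] <- as.integer((p - 1L) * geometry$per_panel) +
        as.integer(row[hit]) * geometry$n_side + as.integer(col[hit]) + 1L
    }
    out
  } else {
    cs <- geometry$crystal
    phi <- atan2(points[, 2], points[, 1]) %% (2 * pi)
    kt0 <- floor(phi / geometry$dphi)   # candidate 0-based transaxial index
    out <- rep(NA_integer_, nrow(points))
    for (dk in c(0, -1, 1)) {
      kt <- (kt0 + dk) %% geometry$nt
      phic <- (kt + 0.5) * geometry$dphi
      rc <- geometry$r_inner + cs$length / 2
      cx <- rc * cos(phic); cy <- rc * sin(phic)
      rad <- cbind(cos(phic), sin(phic))
      tang <- cbind(-sin(phic), cos(phic))
      w1 <- (points[, 1] - cx) * rad[, 1] + (points[, 2] - cy) * rad[, 2]
      w2 <- (points[, 1] - cx) * tang[, 1] + (points[, 2] - cy) * tang[, 2]
      ka <- pmin(pmax(floor((points[, 3] + geometry$axial_fov / 2) /
                              geometry$axial_pitch), 0), geometry$na - 1)
      zc <- -geometry$axial_fov / 2 + (ka + 0.5) * geometry$axial_pitch
      ok <- abs(w1) <= cs$length / 2 & abs(w2) <= cs$cross_section / 2 &
        abs(points[, 3] - zc) <= cs$cross_section / 2
      hit <- which(ok & is.na(out))
      out[hit] <- as.integer(kt[hit]) * geometry$na + as.integer(ka[hit]) + 1L
    }
    out
  }
}

#' Readout group of a crystal
#'
#' At `"crystal"` level this is the identity; at `"submodule"` level
#' crystals are grouped into 5 x 5 blocks (in both scanner types) and the
#' group index is returned.
#'
#' @param geometry A `scanner_geometry`.
#' @param id Flat crystal ids.
#' @param level `"crystal"` or `"submodule"`.
#' @return Integer group ids (a distinct 1-based index space at submodule
#'   level).
#' @export
readout_group <- function(geometry, id, level = c("crystal", "submodule")) {
  level <- match.arg(level)
  if (level == "crystal") return(as.integer(id))
  s <- geometry$submodule
  if (geometry$type == "panel") {
    h <- panel_hier(geometry, id)
    nb <- geometry$n_side %/% s
    brow <- (h$row - 1L) %/% s
    bcol <- (h$col - 1L) %/% s
    as.integer((h$panel - 1L) * nb * nb + brow * nb + bcol + 1L)
  } else {
    h <- ring_hier(geometry, id)
    nbt <- geometry$nt %/% s
    bt <- (h$kt - 1L) %/% s
    ba <- (h$ka - 1L) %/% s
    as.integer(bt * (geometry$na %/% s) + ba + 1L)
  }
}

#' Panel (or sector) of each crystal
#'
#' Used by the coincidence geometry-acceptance test: flat-panel scanners
#' accept any pair of distinct panels; the ring applies a minimum sector
#' difference.
#'
#' @param geometry A `scanner_geometry`.
#' @param id Flat crystal ids.
#' @return Integer panel ids (panel scanner) or sector ids (ring).
#' @export
panel_of <- function(geometry, id) {
  if (geometry$type == "panel") panel_hier(geometry, id)$panel
  else ring_hier(geometry, id)$sector
}

#' Circular sector difference on the reference ring
#'
#' @param geometry A ring `scanner_geometry`.
#' @param id1,id2 Flat crystal ids.
#' @return Circular distance between sector indices, in `[0, 9]` for 19
#'   sectors.
#' @export
sector_difference <- function(geometry, id1, id2) {
  if (geometry$type != "ring")
    stop("sector_difference is only defined for ring geometries")
  s1 <- ring_hier(geometry, id1)$sector
  s2 <- ring_hier(geometry, id2)$sector
  d <- abs(s1 - s2)
  pmin(d, geometry$n_sectors - d)
}
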