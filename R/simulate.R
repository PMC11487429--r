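#' Emit back-to-back annihilation photon pairs
#'
#' The first photon direction is isotropic; the second is anti-parallel,
#' deflected by a non-colinearity angle drawn from a Gaussian of the given
#' FWHM (absolute value as the polar deflection, uniform azimuth). Both
#' photons carry 511 keV.
#'
#' @param points n x 3 matrix of emission points (mm).
#' @param noncolinearity_deg_fwhm FWHM of the acolinearity distribution in
#'   degrees (0.5 by default, the water value).
#' @return List with `dir1`, `dir2` (n x 3 unit vectors).
#' @export
emit_pair <- function(points, noncolinearity_deg_fwhm = 0.5) {
  n <- nrow(rbind(points))
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  d1 <- cbind(s * cos(phi), s * sin(phi), z)
  if (noncolinearity_deg_fwhm <= 0) return(list(dir1 = d1, dir2 = -d1))
  sigma <- noncolinearity_deg_fwhm * pi / 180 / FWHM_SIGMA
  delta <- abs(rnorm(n, 0, sigma))
  psi <- runif(n, 0, 2 * pi)
  # orthonormal frame around -d1
  ref <- cbind(-d1[, 2], d1[, 1], 0)
  small <- abs(d1[, 3]) >= 0.9
  ref[small, ] <- matrix(c(1, 0, 0), sum(small), 3, byrow = TRUE)
  ref <- ref - rowSums(ref * d1) * d1
  ref <- ref / sqrt(rowSums(ref^2))
  e2 <- cbind(d1[, 2] * ref[, 3] - d1[, 3] * ref[, 2],
              d1[, 3] * ref[, 1] - d1[, 1] * ref[, 3],
              d1[, 1] * ref[, 2] - d1[, 2] * ref[, 1])
  d2 <- -cos(delta) * d1 + sin(delta) * (cos(psi) * ref + sin(psi) * e2)
  list(dir1 = d1, dir2 = d2)
}

#' Poisson-process decay times
#'
#' @param total_activity_Bq Source activity (decays per second).
#' @param duration_s Acquisition duration.
#' @param n_decays Optional fixed decay count overriding the Poisson draw
#'   (times still uniform over the acquisition).
#' @return Strictly increasing emission times in ns.
#' @export
generate_decay_times <- function(total_activity_Bq, duration_s, n_decays = NULL) {
  stopifnot(total_activity_Bq >= 0, duration_s >= 0)
  n <- if (is.null(n_decays)) rpois(1, total_activity_Bq * duration_s) else n_decays
  sort(runif(n, 0, duration_s)) * 1e9
}

#' Transport photons through a phantom
#'
#' Woodcock (delta) tracking with exponential free paths, Klein-Nishina
#' Compton scattering and photoelectric absorption; terminates on escape,
#' absorption, energy below the 50 keV cutoff, or more than 5 scatters.
#'
#' @param pos,dir n x 3 matrices: start positions (mm) and unit directions.
#' @param energy_keV Photon energies.
#' @param phantom An `analytic_phantom`.
#' @param e_cutoff_keV,max_scatter Termination parameters.
#' @return List: `escaped` (logical), `pos`/`dir` (position of the last
#'   real interaction and current direction -- the outgoing ray is
#'   guaranteed interaction-free), `energy`, `nscatter`, `path_mm`
#'   (distance travelled up to `pos`).
#' @export
transport_phantom <- function(pos, dir, energy_keV, phantom,
                              e_cutoff_keV = 50, max_scatter = 5) {
  r <- cpp_transport_phantom(rbind(pos), rbind(dir), energy_keV,
                             phantom_matrix(phantom), phantom$bg_idx,
                             phantom_bound_radius(phantom),
                             MATERIAL_MU, MATERIAL_PE_FRAC,
                             MATERIAL_ENERGIES_KEV, e_cutoff_keV,
                             as.integer(max_scatter))
  list(escaped = r$status == 1L, pos = r$pos, dir = r$dir, energy = r$energy,
       nscatter = r$nscatter, path_mm = r$path)
}

#' Transport photons through the detector
#'
#' Ray-traces escaped photons through the crystal volumes (gaps between
#' sparse crystals are vacuum) and samples photoelectric or Compton
#' interactions from the LYSO cross-sections; Compton-scattered photons
#' continue and may deposit in other crystals (inter-crystal scatter).
#'
#' @param pos,dir,energy_keV Photon states (see [transport_phantom()]).
#' @param geometry A `scanner_geometry`.
#' @param e_cutoff_keV,max_scatter Termination parameters; remaining energy
#'   below the cutoff is absorbed locally.
#' @return `data.table` of interactions: `photon` (input row), `crystal`
#'   (flat id), `edep` (keV), `path_mm` (from the input position), plus the
#'   per-photon `escaped_energy` vector as an attribute.
#' @export
transport_detector <- function(pos, dir, energy_keV, geometry,
                               e_cutoff_keV = 50, max_scatter = 5) {
  pos <- rbind(pos); dir <- rbind(dir)
  lyso <- material_index("lyso")
  cs <- geometry$crystal
  r <- if (geometry$type == "panel") {
    cpp_transport_panels(pos, dir, energy_keV, geometry$n_panels,
                         geometry$separation, geometry$extent, cs$pitch,
                         cs$cross_section, cs$length,
                         MATERIAL_MU, MATERIAL_PE_FRAC, MATERIAL_ENERGIES_KEV,
                         lyso, e_cutoff_keV, as.integer(max_scatter))
  } else {
    cpp_transport_ring(pos, dir, energy_keV, geometry$r_inner, cs$length,
                       cs$cross_section, geometry$nt, geometry$na,
                       geometry$axial_fov,
                       MATERIAL_MU, MATERIAL_PE_FRAC, MATERIAL_ENERGIES_KEV,
                       lyso, e_cutoff_keV, as.integer(max_scatter))
  }
  out <- data.table::data.table(photon = r$photon + 1L, crystal = r$crystal,
                                edep = r$edep, path_mm = r$path)
  data.table::setattr(out, "escaped_energy", r$escaped_energy)
  out
}

line_hits_detector <- function(pos, dir, geometry, margin = 5) {
  if (geometry$type == "panel")
    cpp_line_hits_panels(pos, dir, geometry$n_panels, geometry$separation,
                         geometry$extent, geometry$crystal$length, margin)
  else
    cpp_line_hits_ring(pos, dir, geometry$r_inner, geometry$crystal$length,
                       geometry$axial_fov, margin)
}

#' Run a Monte Carlo acquisition
#'
#' Full chain per decay: Poisson emission time, activity-weighted emission
#' point, back-to-back pair with 0.5 degree non-colinearity, phantom
#' transport, detector transport. Processes decays in chunks to bound
#' memory; reproducible under `set.seed()`.
#'
#' @param phantom An `analytic_phantom` with positive activity.
#' @param geometry A `scanner_geometry`.
#' @param duration_s Acquisition duration (used with the phantom activity).
#' @param n_decays Fixed decay count overriding the Poisson draw.
#' @param noncolinearity_deg_fwhm Acolinearity FWHM (degrees).
#' @param trues_only If `TRUE`, events in which either photon interacts in
#'   the phantom are discarded at the point of first interaction, and
#'   events whose emission line cannot geometrically reach two detector
#'   heads are skipped. This is an exact shortcut for studies that
#'   reconstruct true coincidences only; scattered/random bookkeeping is
#'   then unavailable.
#' @param chunk_decays Decays per processing chunk.
#' @return An `acquisition`: list with `interactions` (data.table: `event`,
#'   `crystal`, `edep` keV, `t` ns, `scat` logical phantom-scatter flag of
#'   the depositing photon), `n_decays`, `duration_s`, `activity_Bq`.
#' @export
run_acquisition <- function(phantom, geometry, duration_s = NULL,
                            n_decays = NULL, noncolinearity_deg_fwhm = 0.5,
                            trues_only = FALSE, chunk_decays = 1e6) {
  activity <- phantom_activity(phantom)
  if (is.null(n_decays)) {
    stopifnot(!is.null(duration_s))
    n_decays <- rpois(1, activity * duration_s)
  } else if (is.null(duration_s)) {
    duration_s <- if (activity > 0) n_decays / activity else 1
  }
  n_decays <- as.integer(n_decays)
  empty <- data.table::data.table(event = integer(), crystal = integer(),
                                  edep = numeric(), t = numeric(),
                                  scat = logical())
  if (n_decays == 0)
    return(structure(list(interactions = empty, n_decays = 0L,
                          duration_s = duration_s, activity_Bq = activity,
                          trues_only = trues_only), class = "acquisition"))
  n_chunks <- max(1L, ceiling(n_decays / chunk_decays))
  bounds <- floor(seq(0, n_decays, length.out = n_chunks + 1))
  parts <- vector("list", n_chunks)
  for (ci in seq_len(n_chunks)) {
    ids <- (bounds[ci] + 1L):bounds[ci + 1]
    n <- length(ids)
    tns <- sort(runif(n, 0, duration_s)) * 1e9
    pts <- sample_emission(phantom, n)
    dd <- emit_pair(pts, noncolinearity_deg_fwhm)
    keep <- rep(TRUE, n)
    if (trues_only)
      keep <- as.logical(line_hits_detector(pts, dd$dir1, geometry))
    if (!any(keep)) next
    pos <- rbind(pts[keep, , drop = FALSE], pts[keep, , drop = FALSE])
    dir <- rbind(dd$dir1[keep, , drop = FALSE], dd$dir2[keep, , drop = FALSE])
    ev <- rep(ids[keep], 2)
    t0 <- rep(tns[keep], 2)
    # in trues-only mode any interaction disqualifies the event, so the
    # transport can stop at the first real collision (max_scatter = 0)
    tp <- transport_phantom(pos, dir, rep(511, nrow(pos)), phantom,
                            max_scatter = if (trues_only) 0 else 5)
    esc <- tp$escaped & (if (trues_only) tp$nscatter == 0L else TRUE)
    if (trues_only) {
      # both photons of an event must escape unscattered; photon blocks are
      # stacked [all photon 1; all photon 2] in matching event order
      m <- sum(keep)
      pair_ok <- esc[seq_len(m)] & esc[m + seq_len(m)]
      esc <- rep(pair_ok, 2)
    }
    if (!any(esc)) next
    ints <- transport_detector(tp$pos[esc, , drop = FALSE],
                               tp$dir[esc, , drop = FALSE],
                               tp$energy[esc], geometry)
    if (nrow(ints) == 0) next
    pev <- ev[esc]; pt0 <- t0[esc]
    ppath <- tp$path_mm[esc]; pscat <- tp$nscatter[esc] > 0L
    ints[, `:=`(event = pev[photon],
                t = pt0[photon] + (ppath[photon] + path_mm) / C_MM_PER_NS,
                scat = pscat[photon])]
    parts[[ci]] <- ints[, .(event, crystal, edep, t, scat)]
  }
  parts <- parts[!vapply(parts, is.null, TRUE)]
  ints <- if (length(parts)) data.table::rbindlist(parts) else empty
  structure(list(interactions = ints, n_decays = n_decays,
                 duration_s = duration_s, activity_Bq = activity,
                 trues_only = trues_only),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  cat(sprintf("<acquisition: %d decays over %.3g s (%.3g Bq), %d crystal interactions%s>\n",
              x$n_decays, x$duration_s, x$activity_Bq, nrow(x$interactions),
              if (isTRUE(x$trues_only)) ", trues-only" else ""))
  invisible(x)
}
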