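#' Coincidence / digitizer policy
#'
#' Bundles the digitizer and sorter parameters. The defaults follow the
#' flat-panel scanner (2 ns window, crystal-level winner-take-all readout,
#' 435--585 keV window, any pair of distinct panels); [ring_policy()]
#' gives the reference-scanner settings (4.7 ns window, submodule-level
#' take-energy-centroid readout, minimum sector difference 4).
#'
#' @param window_ns Coincidence window; also used as the readout
#'   integration window.
#' @param level Readout level: `"crystal"` or `"submodule"`.
#' @param energy_policy `"winner"` (winner-take-all) or `"centroid"`
#'   (take-energy-centroid, snapped to the nearest crystal).
#' @param e_low_keV,e_high_keV Energy window.
#' @param energy_resolution Fractional FWHM at 511 keV.
#' @param ctr_ps Coincidence time resolution (FWHM of the pair time
#'   difference).
#' @param min_sector_diff Minimum circular sector difference (ring only).
#' @return A `coincidence_policy`.
#' @export
coincidence_policy <- function(window_ns = 2, level = "crystal",
                               energy_policy = "winner",
                               e_low_keV = 435, e_high_keV = 585,
                               energy_resolution = 0.10, ctr_ps = 75,
                               min_sector_diff = 4) {
  stopifnot(window_ns > 0, level %in% c("crystal", "submodule"),
            energy_policy %in% c("winner", "centroid"))
  structure(list(window_ns = window_ns, level = level,
                 energy_policy = energy_policy, e_low = e_low_keV,
                 e_high = e_high_keV, energy_resolution = energy_resolution,
                 ctr_ps = ctr_ps, min_sector_diff = min_sector_diff),
            class = "coincidence_policy")
}

#' @rdname coincidence_policy
#' @export
ring_policy <- function(ctr_ps = 214) {
  coincidence_policy(window_ns = 4.7, level = "submodule",
                     energy_policy = "centroid", ctr_ps = ctr_ps,
                     min_sector_diff = 4)
}

#' Group crystal interactions into singles
#'
#' Deposits that share a readout group (crystal, or 5 x 5 submodule block)
#' and fall within the integration window are summed into one single. The
#' position carrier is the crystal with the largest deposit
#' (winner-take-all) or the crystal nearest the energy-weighted centroid;
#' the timestamp is that of the earliest deposit.
#'
#' @param interactions data.table with `event`, `crystal`, `edep`, `t`,
#'   `scat` (see [run_acquisition()]).
#' @param geometry A `scanner_geometry`.
#' @param level,energy_policy,integration_ns Readout parameters.
#' @return data.table of singles: `crystal`, `energy`, `t`, `event`,
#'   `scat`, `panel`.
#' @export
group_to_singles <- function(interactions, geometry,
                             level = "crystal", energy_policy = "winner",
                             integration_ns = 2) {
  if (nrow(interactions) == 0)
    return(data.table::data.table(crystal = integer(), energy = numeric(),
                                  t = numeric(), event = integer(),
                                  scat = logical(), panel = integer()))
  x <- data.table::copy(interactions)
  x[, grp := readout_group(geometry, crystal, level)]
  data.table::setorder(x, grp, t)
  x[, cl := cumsum(c(TRUE, diff(t) > integration_ns | diff(grp) != 0))]
  if (energy_policy == "winner" || level == "crystal") {
    # winner-take-all via GForce-friendly aggregation: order each cluster
    # by decreasing deposit so "first" is the winning crystal
    data.table::setorder(x, cl, -edep)
    s <- x[, .(crystal = data.table::first(crystal),
               event = data.table::first(event),
               energy = sum(edep), t = min(t), scat = max(scat)),
           by = cl]
    s[, scat := scat > 0L]
  } else {
    cc <- crystal_center(geometry, x$crystal)
    x[, `:=`(cx = cc[, 1], cy = cc[, 2], cz = cc[, 3])]
    s <- x[, {
      e <- sum(edep)
      p <- c(sum(edep * cx), sum(edep * cy), sum(edep * cz)) / e
      # snap the centroid to the nearest crystal of the group
      cand <- unique(crystal)
      cen <- crystal_center(geometry, cand)
      d2 <- rowSums((cen - matrix(p, length(cand), 3, byrow = TRUE))^2)
      w <- which.max(edep)
      .(crystal = cand[which.min(d2)], energy = e, t = min(t),
        event = event[w], scat = any(scat))
    }, by = cl]
  }
  s[, cl := NULL]
  s[, panel := panel_of(geometry, crystal)]
  data.table::setorder(s, t)
  s[]
}

#' Gaussian energy blur
#'
#' FWHM scales as `resolution * 511 * sqrt(E / 511)` (1/sqrt(E)
#' fractional-resolution scaling), so the fractional FWHM equals
#' `resolution` at 511 keV.
#'
#' @param energy_keV Deposited energies.
#' @param resolution Fractional FWHM at 511 keV.
#' @return Blurred energies (keV).
#' @export
blur_energy <- function(energy_keV, resolution = 0.10) {
  if (resolution <= 0) return(energy_keV)
  fwhm <- resolution * 511 * sqrt(pmax(energy_keV, 0) / 511)
  energy_keV + rnorm(length(energy_keV), 0, fwhm / FWHM_SIGMA)
}

#' Gaussian time blur
#'
#' Each single is jittered with sigma `CTR / (2 sqrt(2 ln 2)) / sqrt(2)`
#' so the pair time-difference distribution has FWHM equal to the CTR.
#'
#' @param t_ns Timestamps (ns).
#' @param ctr_ps Coincidence time resolution (ps).
#' @return Blurred timestamps (ns).
#' @export
blur_time <- function(t_ns, ctr_ps) {
  stopifnot(ctr_ps >= 0)
  if (ctr_ps == 0) return(t_ns)
  sigma_ns <- ctr_ps * 1e-3 / FWHM_SIGMA / sqrt(2)
  t_ns + rnorm(length(t_ns), 0, sigma_ns)
}

#' Apply the energy window
#'
#' @param singles data.table with an `energy` column.
#' @param low,high Window bounds (keV), inclusive.
#' @export
apply_energy_window <- function(singles, low = 435, high = 585) {
  singles[energy >= low & energy <= high]
}

#' Pair singles into coincidences
#'
#' Sliding-window sorter: a window opens at the earliest unconsumed single;
#' exactly two singles form a candidate pair, which must pass the geometry
#' acceptance (different panels, or circular sector difference at least
#' `min_sector_diff` on the ring); windows with more than two singles are
#' discarded entirely. The truth class is attached from the event ids and
#' phantom-scatter flags.
#'
#' @param singles Time-sorted singles (see [group_to_singles()]).
#' @param geometry A `scanner_geometry`.
#' @param policy A [coincidence_policy()].
#' @return data.table of coincidences: crystal ids `id1`/`id2`, timestamps,
#'   `dt_ns = t1 - t2`, and `class` in true/scattered/random.
#' @export
sort_coincidences <- function(singles, geometry, policy = coincidence_policy()) {
  if (nrow(singles) == 0 || is.unsorted(singles$t))
    if (nrow(singles) > 0) stop("singles must be time-sorted")
  mode <- if (geometry$type == "panel") 0L else 1L
  ngr <- if (geometry$type == "panel") geometry$n_panels else geometry$n_sectors
  pr <- cpp_sort_coincidences(singles$t, as.integer(singles$panel),
                              policy$window_ns, mode, ngr,
                              as.integer(policy$min_sector_diff))
  i <- pr[, 1]; j <- pr[, 2]
  out <- data.table::data.table(
    id1 = singles$crystal[i], id2 = singles$crystal[j],
    t1 = singles$t[i], t2 = singles$t[j],
    dt_ns = singles$t[i] - singles$t[j],
    event1 = singles$event[i], event2 = singles$event[j],
    scat = singles$scat[i] | singles$scat[j])
  out[, class := data.table::fifelse(event1 != event2, "random",
                                     data.table::fifelse(scat, "scattered", "true"))]
  out[, c("scat") := NULL]
  out[]
}

#' True / scattered / random count rates
#'
#' @param coincidences Output of [sort_coincidences()].
#' @param duration_s Acquisition duration.
#' @return List with `T`, `S`, `R` rates in counts per second.
#' @export
count_rates <- function(coincidences, duration_s) {
  stopifnot(duration_s > 0)
  n <- table(factor(coincidences$class, levels = c("true", "scattered", "random")))
  list(T = as.numeric(n[["true"]]) / duration_s,
       S = as.numeric(n[["scattered"]]) / duration_s,
       R = as.numeric(n[["random"]]) / duration_s)
}

#' Digitize an acquisition into list-mode coincidences
#'
#' Full digitizer chain in GATE order: readout grouping, energy blur,
#' energy window, time blur, time sort, coincidence sorting.
#'
#' @param acq An [run_acquisition()] result.
#' @param geometry A `scanner_geometry`.
#' @param policy A [coincidence_policy()].
#' @return Coincidence data.table (see [sort_coincidences()]).
#' @export
process_acquisition <- function(acq, geometry, policy = coincidence_policy()) {
  s <- group_to_singles(acq$interactions, geometry, policy$level,
                        policy$energy_policy, policy$window_ns)
  s[, energy := blur_energy(energy, policy$energy_resolution)]
  s <- apply_energy_window(s, policy$e_low, policy$e_high)
  s[, t := blur_time(t, policy$ctr_ps)]
  data.table::setorder(s, t)
  sort_coincidences(s, geometry, policy)
}

#' Write / read a list-mode coincidence file (CSV)
#'
#' Columns: `id1`, `id2` (flat crystal indices), `t1`, `t2` (ns),
#' `dt_ns`, `class`.
#'
#' @param coincidences Coincidence table.
#' @param path CSV path.
#' @export
write_listmode <- function(coincidences, path) {
  data.table::fwrite(coincidences[, .(id1, id2, t1, t2, dt_ns, class)], path)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) data.table::fread(path)
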