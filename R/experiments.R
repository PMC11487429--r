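#' Parse a scanner configuration name
#'
#' Grammar: `CS<cross-section>_L<length>_CTR<ctr>[_pitch<p>][submod]`, e.g.
#' `CS3_L10_CTR75` (3 x 3 mm crystals, 10 mm long, 75 ps CTR, default
#' 3 mm pitch, crystal-level readout) or `CS1.5_L10_CTR75_pitch2` and
#' `CS3_L10_CTR75submod`. `"reference"` names the reference ring scanner.
#'
#' @param text Configuration name.
#' @return A `scanner_config_name`: list with `cross_section`, `length`,
#'   `ctr`, `pitch`, `level` (and `reference` flag).
#' @export
parse_config_name <- function(text) {
  if (identical(text, "reference"))
    return(structure(list(reference = TRUE, ctr = 214, level = "submodule"),
                     class = "scanner_config_name"))
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  pat <- paste0("^CS", num, "_L", num, "_CTR", num,
                "(?:_pitch", num, ")?(submod)?$")
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) == 0)
    stop("malformed configuration name '", text,
         "'; expected CS<cs>_L<len>_CTR<ps>[_pitch<p>][submod]")
  cs <- as.numeric(m[2]); len <- as.numeric(m[3]); ctr <- as.numeric(m[4])
  pitch <- if (nzchar(m[5])) as.numeric(m[5]) else 3
  structure(list(reference = FALSE, cross_section = cs, length = len,
                 ctr = ctr, pitch = pitch,
                 level = if (nzchar(m[6])) "submodule" else "crystal"),
            class = "scanner_config_name")
}

#' @rdname parse_config_name
#' @param x A `scanner_config_name`.
#' @export
format_config_name <- function(x) {
  if (isTRUE(x$reference)) return("reference")
  fmt <- function(v) sub("\\.0+$", "", format(v, trim = TRUE))
  paste0("CS", fmt(x$cross_section), "_L", fmt(x$length), "_CTR", fmt(x$ctr),
         if (x$pitch != 3) paste0("_pitch", fmt(x$pitch)) else "",
         if (x$level == "submodule") "submod" else "")
}

#' Build scanner geometry and policy from a configuration name
#'
#' @param name Configuration name string or [parse_config_name()] result.
#' @return List with `geometry`, `policy`, `name`.
#' @export
build_scanner <- function(name) {
  cfg <- if (inherits(name, "scanner_config_name")) name else parse_config_name(name)
  if (isTRUE(cfg$reference)) {
    list(geometry = build_reference_ring(), policy = ring_policy(),
         name = "reference")
  } else {
    geom <- build_flat_panel(crystal_spec(cfg$cross_section, cfg$length, cfg$pitch))
    pol <- coincidence_policy(window_ns = 2, level = cfg$level,
                              energy_policy = "winner", ctr_ps = cfg$ctr)
    list(geometry = geom, policy = pol, name = format_config_name(cfg))
  }
}

#' Relative scintillator volume table
#'
#' Analytic columns of the design-comparison summary: total crystal volume
#' per configuration and its ratio to the reference scanner.
#'
#' @param names Character vector of configuration names.
#' @return data.frame: `name`, `volume_dm3`, `relative_volume_pct`.
#' @export
relative_volume_table <- function(names = c("CS3_L10_CTR75", "CS2.5_L10_CTR75",
                                            "CS2_L10_CTR75",
                                            "CS1.5_L10_CTR75_pitch2",
                                            "CS3_L7.5_CTR75", "CS3_L5_CTR75")) {
  ref <- total_crystal_volume(build_reference_ring())
  rows <- lapply(names, function(nm) {
    v <- total_crystal_volume(build_scanner(nm)$geometry)
    data.frame(name = nm, volume_dm3 = v, relative_volume_pct = 100 * v / ref)
  })
  out <- do.call(rbind, rows)
  rbind(data.frame(name = "reference", volume_dm3 = ref,
                   relative_volume_pct = 100), out)
}

#' Design-comparison summary table
#'
#' Aggregates the headline per-scanner metrics into one table: relative
#' scintillator volume (analytic), spatial resolution in X for a source
#' 37 mm off-center (desk-scale simulate/reconstruct/fit), total system
#' sensitivity at the FOV center, and NECR_TOF at 10 kBq/mL. The
#' contrast-at-5%-variability column of the published layout needs
#' paper-scale statistics and is not computed here (see the methods
#' vignette).
#'
#' @param scanners Configuration names.
#' @param scale Event-count scale factor in (0, 1] applied to every
#'   simulation-backed column.
#' @param resolution Include the (slow) resolution column.
#' @return data.frame, one row per scanner.
#' @export
table1 <- function(scanners = c("reference", "CS3_L10_CTR75",
                                "CS3_L10_CTR75submod", "CS2.5_L10_CTR75",
                                "CS2_L10_CTR75", "CS1.5_L10_CTR75_pitch2",
                                "CS3_L10_CTR100", "CS3_L10_CTR150",
                                "CS3_L7.5_CTR75", "CS3_L5_CTR75"),
                   scale = 1, resolution = FALSE) {
  ref_vol <- total_crystal_volume(build_reference_ring())
  rows <- lapply(scanners, function(nm) {
    sc <- build_scanner(nm)
    sens <- point_sensitivity(sc$geometry, sc$policy, c(0, 0, 0),
                              n_decays = ceiling(1e5 * scale))
    nec <- necr_study(sc$geometry, sc$policy, activities_kBq_mL = 10,
                      n_decays = ceiling(1.2e6 * scale))
    res <- if (resolution) {
      rr <- resolution_repeats(sc$geometry, sc$policy, c(37, 0, 0),
                               n_repeats = 2,
                               n_true_target = ceiling(4e5 * scale))
      rr$fwhm[1]
    } else NA_real_
    data.frame(name = nm,
               relative_volume_pct = 100 * total_crystal_volume(sc$geometry) / ref_vol,
               resolution_x_mm = res,
               sensitivity_kcps_MBq = sens,
               necr_tof_cps = nec$necr_tof)
  })
  do.call(rbind, rows)
}

#' Run a configured study
#'
#' Desk-scale orchestration of the individual studies. Results are written
#' as CSV tables plus a JSON provenance record (configuration, seed, event
#' counts, scale factors) under `out_dir`.
#'
#' @param kind One of `"resolution-single"`, `"resolution-grid"`, `"iq"`,
#'   `"sensitivity"`, `"necr"`, `"qualitative"`.
#' @param scanner Configuration name (see [parse_config_name()]).
#' @param seed RNG seed (full pipeline is deterministic given the seed).
#' @param out_dir Output directory (created); `NULL` returns results only.
#' @param scale Event-count scale factor relative to the built-in
#'   desk-scale defaults, in (0, 1].
#' @param ... Study-specific overrides passed to the underlying functions.
#' @return The study result (data.frame), invisibly when written.
#' @export
run_study <- function(kind = c("resolution-single", "resolution-grid", "iq",
                               "sensitivity", "necr", "qualitative"),
                      scanner = "CS3_L10_CTR75", seed = 1, out_dir = NULL,
                      scale = 1, ...) {
  kind <- match.arg(kind)
  stopifnot(scale > 0, scale <= 1)
  set.seed(seed)
  sc <- build_scanner(scanner)
  res <- switch(kind,
    "resolution-single" = resolution_study(
      sc$geometry, sc$policy, positions = matrix(c(0, 10, 0), 1),
      n_true_target = ceiling(2e4 * scale), ...),
    "resolution-grid" = {
      grid_ph <- point_source_grid(...)
      resolution_study(sc$geometry, sc$policy,
                       positions = attr(grid_ph, "positions"),
                       n_true_target = ceiling(2e4 * scale))
    },
    "iq" = iq_study(sc$geometry, sc$policy, n_decays = ceiling(2.6e8 * scale), ...),
    "sensitivity" = sensitivity_scan(sc$geometry, sc$policy,
                                     n_decays = ceiling(2e4 * scale), ...),
    "necr" = necr_study(sc$geometry, sc$policy,
                        n_decays = ceiling(2e6 * scale), ...),
    "qualitative" = qualitative_study(sc$geometry, sc$policy,
                                      n_decays = ceiling(2e6 * scale), ...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, paste0(kind, "_", sc$name, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, scanner = sc$name, seed = seed, scale = scale,
           package_version = as.character(utils::packageVersion("panelpet")),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, paste0(kind, "_", sc$name, "_provenance.json")),
      auto_unbox = TRUE)
    return(invisible(res))
  }
  res
}

# NEMA IQ pipeline: phantom + normalization-cube acquisitions, 50-iteration
# MLEM at 3 mm voxels, normalization correction, filter sweep. Prebuilt
# acquisitions can be passed in (e.g. to digitize the same interaction
# stream at several CTRs). At 3 mm voxels the crystal aperture matches the
# voxel size, so the single center ray is adequate (aperture_rays = 1).
iq_study <- function(geometry, policy, n_decays = 2.6e8, n_iter = 50,
                     voxel_mm = 3, fov_mm = 360, norm_decays = 2e7,
                     filter_fwhms_mm = c(0, 2, 4, 6, 8),
                     sensitivity = NULL, acq = NULL, norm_acq = NULL,
                     aperture_rays = 1) {
  ph <- nema_iq_phantom()
  # odd voxel count: the central slice then cuts the sphere equators
  nd <- round(fov_mm / voxel_mm)
  grid <- image_grid_centered(voxel_mm, nd + (1 - nd %% 2))
  if (is.null(sensitivity))
    sensitivity <- compute_sensitivity(geometry, grid, n_samples = 4e6,
                                       smooth_fwhm_mm = 2 * voxel_mm)
  if (is.null(acq))
    acq <- run_acquisition(ph, geometry, n_decays = as.integer(n_decays),
                           trues_only = TRUE)
  co <- process_acquisition(acq, geometry, policy)
  co <- co[class == "true"]
  img <- mlem(co, geometry, grid, n_iter = n_iter, tof = TRUE,
              ctr_ps = policy$ctr_ps, sensitivity = sensitivity,
              aperture_rays = aperture_rays)
  if (is.null(norm_acq))
    norm_acq <- run_acquisition(normalization_cube(), geometry,
                                n_decays = as.integer(norm_decays),
                                trues_only = TRUE)
  nco <- process_acquisition(norm_acq, geometry, policy)
  nimg <- mlem(nco[class == "true"], geometry, grid, n_iter = n_iter,
               tof = TRUE, ctr_ps = policy$ctr_ps, sensitivity = sensitivity,
               aperture_rays = aperture_rays)
  corrected <- normalize_by_homogeneous(img, nimg, filter_fwhm_mm = 15)
  sw <- iq_filter_sweep(corrected, attr(ph, "sphere_centers"),
                        attr(ph, "sphere_diameters"),
                        ratio = attr(ph, "ratio"),
                        filter_fwhms_mm = filter_fwhms_mm)
  sw$n_true <- nrow(co)
  attr(sw, "image") <- corrected
  sw
}

# hot-rod phantom reconstruction + SSIM sweep against the voxelized truth
qualitative_study <- function(geometry, policy, n_decays = 2e6, n_iter = 50,
                              voxel_mm = 1, filter_fwhms_mm = 0:8) {
  ph <- derenzo_phantom()
  acq <- run_acquisition(ph, geometry, n_decays = as.integer(n_decays),
                         trues_only = TRUE)
  co <- process_acquisition(acq, geometry, policy)
  grid <- image_grid_centered(voxel_mm, c(128, 128, 32))
  img <- mlem(co[class == "true"], geometry, grid, n_iter = n_iter,
              tof = TRUE, ctr_ps = policy$ctr_ps,
              n_samples = 2e6, smooth_fwhm_mm = 3 * voxel_mm)
  ref <- voxelize(ph, grid, supersample = 2)
  ssim_curve(img, ref, filter_fwhms_mm = filter_fwhms_mm)
}

#' Command-line entry point
#'
#' Minimal CLI mirroring [run_study()]:
#' `panelpet <kind> --scanner NAME --seed N --out DIR [--scale S]`.
#' An executable wrapper is installed under `exec/panelpet`.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @export
panelpet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    cat("usage: panelpet <kind> [--scanner NAME] [--seed N] [--out DIR] [--scale S]\n")
    return(invisible(1L))
  }
  kind <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  res <- run_study(kind, scanner = opt("--scanner", "CS3_L10_CTR75"),
                   seed = as.integer(opt("--seed", "1")),
                   out_dir = opt("--out", NULL),
                   scale = as.numeric(opt("--scale", "1")))
  if (is.null(opt("--out", NULL))) print(res)
  invisible(0L)
}
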