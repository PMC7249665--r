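# End-to-end study pipeline: simulate -> select -> reconstruct -> DEW -> ROI.

#' Run a full simultaneous-imaging study
#'
#' Executes the complete pipeline described by a [study_config()]: simulate
#' each source (cached list-mode files in \code{outdir} are reused when
#' \code{reuse_cache}), merge, apply the standard selection per energy
#' window, reconstruct backprojection and ML-EM images for the photo-peak
#' and scatter windows, form DEW images, and integrate the ROIs. When
#' \code{outdir} is given, every product is written there (list-mode TSV,
#' spectra TSV, images as text + TIFF, ROI table TSV) together with the
#' resolved configuration and a JSON run manifest with seeds, software
#' versions and per-stage event counts.
#'
#' @param config a \code{cc_config}.
#' @param outdir output directory, or \code{NULL} to return results only.
#' @param arm_params a [voigt_params()]; if \code{NULL}, the ARM kernel is
#'   calibrated from a dedicated clean point-source run at the low-energy
#'   source position.
#' @param methods reconstruction methods to run.
#' @param reuse_cache reuse per-source list-mode files found in
#'   \code{outdir}.
#' @param quiet suppress progress messages.
#' @return A list with \code{events} (merged), \code{spectrum},
#'   \code{selected} (per window), \code{images} (per window and method),
#'   \code{dew} (per method), \code{roi_table}, \code{arm_params} and
#'   \code{counters}.
#' @export
run_study <- function(config, outdir = NULL, arm_params = NULL,
                      methods = c("bp", "mlem"), reuse_cache = FALSE,
                      quiet = FALSE) {
  stopifnot(inherits(config, "cc_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  obj <- .config_objects(config)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- simulate (or reuse) each source -------------------------------------
  per_source <- vector("list", length(obj$sources))
  for (i in seq_along(obj$sources)) {
    src <- obj$sources[[i]]
    cache <- if (!is.null(outdir)) {
      file.path(outdir, sprintf("listmode_%s.tsv", src$label))
    }
    if (reuse_cache && !is.null(cache) && file.exists(cache)) {
      say("reusing cached list-mode data for %s", src$label)
      per_source[[i]] <- read_listmode(cache)
      next
    }
    say("simulating %s (%.3g primaries)", src$label, src$n_photons)
    ev <- simulate_camera(src, obj$phantom, obj$camera, obj$response,
                          seed = config$seed + 7919L * i,
                          max_phantom_scatters = config$simulate$max_phantom_scatters,
                          force_detection = config$simulate$force_detection,
                          fluorescence_prob = config$simulate$fluorescence_prob,
                          quiet = quiet)
    per_source[[i]] <- ev
    if (!is.null(cache)) write_listmode(ev, cache)
  }
  events <- merge_listmode(per_source)
  counters <- lapply(per_source, attr, "counters")

  spectrum <- energy_spectrum(events, bin_width = 1, range = c(0, 600))

  # --- selection per window ------------------------------------------------
  selected <- lapply(obj$windows, function(w) {
    select_events(events, w, quiet = quiet)
  })
  stage_counts <- list(
    merged = nrow(events),
    veto_survivors = nrow(reject_fluorescence(events)),
    physical = nrow(drop_unphysical(reject_fluorescence(events), quiet = TRUE)),
    selected = vapply(selected, nrow, integer(1)))

  # --- ARM kernel ----------------------------------------------------------
  if (is.null(arm_params)) {
    rcfg <- config$reconstruction
    if (is.finite(rcfg$arm_sigma_deg %||% NA) &&
        is.finite(rcfg$arm_gamma_deg %||% NA)) {
      arm_params <- voigt_params(rcfg$arm_sigma_deg * pi / 180,
                                 rcfg$arm_gamma_deg * pi / 180)
    } else {
      say("calibrating ARM kernel from a point-source run")
      lowE <- obj$sources[[1]]
      cal_src <- source_spec(lowE$energy_kev, lowE$position,
                             n_photons = 2e6, emission_mode = "cone_biased",
                             cone_fraction = 1,
                             cone_half_angle_rad = lowE$cone_half_angle_rad)
      cal <- simulate_camera(cal_src, obj$phantom, obj$camera, obj$response,
                             seed = config$seed + 104729L, quiet = TRUE)
      cal <- select_events(cal, obj$windows$photopeak, quiet = TRUE)
      arm_params <- calibrate_arm(cal, lowE$position)
      say("ARM fit: sigma %.3f deg, gamma %.3f deg",
          arm_params$sigma * 180 / pi, arm_params$gamma * 180 / pi)
    }
  }

  # --- reconstruction ------------------------------------------------------
  iterations <- config$reconstruction$iterations
  images <- list()
  for (wname in names(selected)) {
    for (m in methods) {
      say("reconstructing %s / %s (%d events)", wname, m,
          nrow(selected[[wname]]))
      img <- if (m == "bp") {
        backproject(selected[[wname]], obj$grid, arm_params)
      } else {
        mlem(selected[[wname]], obj$grid, arm_params,
             iterations = iterations)
      }
      images[[paste(wname, m, sep = "_")]] <- img
    }
  }

  # --- DEW + ROI -----------------------------------------------------------
  k <- config$reconstruction$k %||% 1.0
  dew <- list()
  for (m in methods) {
    dew[[m]] <- dew_subtract(images[[paste0("photopeak_", m)]],
                             images[[paste0("scatter_", m)]], k = k)
  }
  roi_rows <- crosstalk_curves(list(c(list(ratio = NA_real_), dew)),
                               roi_left = obj$rois$left,
                               roi_right = obj$rois$right)
  roi_rows$ratio <- NULL

  # --- outputs -------------------------------------------------------------
  if (!is.null(outdir)) {
    write_listmode(events, file.path(outdir, "listmode_merged.tsv"))
    write.table(spectrum, file.path(outdir, "spectrum.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(images)) {
      write_image(images[[nm]], file.path(outdir, paste0(nm, ".txt")),
                  tiff_path = file.path(outdir, paste0(nm, ".tif")))
    }
    for (m in names(dew)) {
      write_image(dew[[m]]$dew_image,
                  file.path(outdir, paste0("dew_", m, ".txt")),
                  tiff_path = file.path(outdir, paste0("dew_", m, ".tif")))
    }
    write.table(roi_rows, file.path(outdir, "roi_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_study_config(config, file.path(outdir, "config_resolved.yaml"))
    manifest <- list(
      package_version = as.character(packageVersion("ccdew")),
      r_version = R.version.string,
      seed = config$seed,
      arm_sigma_rad = arm_params$sigma, arm_gamma_rad = arm_params$gamma,
      k = k, stage_counts = stage_counts)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(events = events, spectrum = spectrum, selected = selected,
       images = images, dew = dew, roi_table = roi_rows,
       arm_params = arm_params, counters = counters,
       stage_counts = stage_counts)
}

#' Crosstalk curves versus activity ratio
#'
#' Repeats the merged-source study over a set of high-to-low activity
#' ratios (photon-budget ratios) and tabulates the left/right ROI integrals
#' of the control and DEW images — the quantitative crosstalk summary of the
#' reference study. The low-energy source data are simulated once and
#' reused; the high-energy budget is scaled per ratio.
#'
#' @param config a \code{cc_config}; \code{config$sources[[1]]} is the fixed
#'   low-energy source, \code{config$sources[[2]]} the high-energy source
#'   whose budget is set to \code{ratio * n_photons_low} per run.
#' @param ratios numeric vector of activity ratios (>= 0; 0 means the
#'   high-energy source is absent).
#' @param arm_params a [voigt_params()] used for every reconstruction (one
#'   kernel, as in the reference analysis); if \code{NULL} it is calibrated
#'   once from the low-energy source.
#' @param methods reconstruction methods.
#' @param quiet suppress progress messages.
#' @return A list with \code{curves} (the [crosstalk_curves()] tibble) and
#'   \code{runs} (per-ratio \code{cc_dew} objects).
#' @export
crosstalk_study <- function(config, ratios, arm_params = NULL,
                            methods = c("bp", "mlem"), quiet = FALSE) {
  stopifnot(inherits(config, "cc_config"), length(ratios) >= 1,
            all(ratios >= 0))
  methods <- match.arg(methods, several.ok = TRUE)
  obj <- .config_objects(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  low <- obj$sources[[1]]
  high <- obj$sources[[2]]
  say("simulating fixed low-energy source (%.3g primaries)", low$n_photons)
  ev_low <- simulate_camera(low, obj$phantom, obj$camera, obj$response,
                            seed = config$seed + 7919L,
                            max_phantom_scatters = config$simulate$max_phantom_scatters,
                            force_detection = config$simulate$force_detection,
                            fluorescence_prob = config$simulate$fluorescence_prob,
                            quiet = TRUE)
  if (is.null(arm_params)) {
    cal <- select_events(ev_low, obj$windows$photopeak, quiet = TRUE)
    arm_params <- calibrate_arm(cal, low$position)
    say("ARM fit: sigma %.3f deg, gamma %.3f deg",
        arm_params$sigma * 180 / pi, arm_params$gamma * 180 / pi)
  }
  iterations <- config$reconstruction$iterations
  k <- config$reconstruction$k %||% 1.0

  runs <- vector("list", length(ratios))
  for (ir in seq_along(ratios)) {
    ratio <- ratios[ir]
    if (ratio > 0) {
      nh <- max(1, round(ratio * low$n_photons))
      say("ratio %.3g: simulating high-energy source (%.3g primaries)",
          ratio, nh)
      src_h <- source_spec(high$energy_kev, high$position, nh,
                           emission_mode = high$emission_mode,
                           cone_half_angle_rad = high$cone_half_angle_rad,
                           cone_fraction = high$cone_fraction,
                           label = high$label)
      ev_h <- simulate_camera(src_h, obj$phantom, obj$camera, obj$response,
                              seed = config$seed + 15485863L + ir,
                              max_phantom_scatters = config$simulate$max_phantom_scatters,
                              force_detection = config$simulate$force_detection,
                              fluorescence_prob = config$simulate$fluorescence_prob,
                              quiet = TRUE)
      ev <- merge_listmode(ev_low, ev_h)
    } else {
      ev <- ev_low
    }
    entry <- list(ratio = ratio)
    for (m in methods) {
      sel_p <- select_events(ev, obj$windows$photopeak, quiet = TRUE)
      sel_s <- select_events(ev, obj$windows$scatter, quiet = TRUE)
      say("ratio %.3g / %s: %d photo-peak, %d scatter events", ratio, m,
          nrow(sel_p), nrow(sel_s))
      rec <- function(sel) {
        if (m == "bp") backproject(sel, obj$grid, arm_params)
        else mlem(sel, obj$grid, arm_params, iterations = iterations)
      }
      entry[[m]] <- dew_subtract(rec(sel_p), rec(sel_s), k = k)
    }
    runs[[ir]] <- entry
  }
  list(curves = crosstalk_curves(runs, obj$rois$left, obj$rois$right),
       runs = runs, arm_params = arm_params)
}
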