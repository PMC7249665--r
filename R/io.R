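# List-mode TSV format, image output, and study configuration files.

#' Write list-mode events to TSV
#'
#' Canonical columnar text format: one event per row, tab separated, header
#' line naming the columns, energies in keV with at least 3 decimals,
#' missing truth fields written as \code{NA}.
#'
#' @param events list-mode events tibble.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_listmode <- function(events, path) {
  df <- as.data.frame(events[, .listmode_cols])
  for (col in c("x1", "y1", "z1", "x2", "y2", "z2", "E1", "E2")) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  df$weight <- sprintf("%.10g", df$weight)
  df$truth_primary_energy <- ifelse(is.na(df$truth_primary_energy), "NA",
                                    sprintf("%.4f", df$truth_primary_energy))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read list-mode events from TSV
#'
#' Inverse of [write_listmode()]; malformed rows (missing columns,
#' non-numeric or non-positive energies) are rejected with their line
#' numbers. A header-only file yields an empty event table.
#'
#' @param path input file.
#' @return A list-mode events tibble.
#' @export
read_listmode <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(truth_source_id = "character"))
  missing_cols <- setdiff(.listmode_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("list-mode file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(.empty_events())
  num_cols <- c("x1", "y1", "z1", "E1", "x2", "y2", "z2", "E2", "weight")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s at line %d of %s", col, bad[1] + 1, path))
    }
    df[[col]] <- v
  }
  bad <- which(df$E1 <= 0 | df$E2 <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive energy at line %d of %s", bad[1] + 1, path))
  }
  bad <- which(!(df$layer %in% 1:3))
  if (length(bad) > 0) {
    stop(sprintf("absorber layer outside 1..3 at line %d of %s", bad[1] + 1, path))
  }
  tibble::tibble(
    event_id = as.integer(df$event_id), x1 = df$x1, y1 = df$y1, z1 = df$z1,
    E1 = df$E1, layer = as.integer(df$layer), x2 = df$x2, y2 = df$y2,
    z2 = df$z2, E2 = df$E2, weight = df$weight,
    truth_source_id = df$truth_source_id,
    truth_primary_energy = suppressWarnings(as.numeric(df$truth_primary_energy)),
    truth_n_phantom_scatters = as.integer(df$truth_n_phantom_scatters),
    truth_full_absorption = as.logical(df$truth_full_absorption),
    truth_si_first = as.logical(df$truth_si_first))
}

#' Merge list-mode datasets
#'
#' Concatenates event tables (e.g. the two single-isotope runs of a
#' simultaneous-imaging study) and renumbers \code{event_id}. Because the
#' selection filters are row-wise, merging commutes with selection.
#'
#' @param ... list-mode events tibbles (or a single list of them).
#' @return The merged tibble.
#' @export
merge_listmode <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  ev <- do.call(rbind, parts)
  ev$event_id <- seq_len(nrow(ev))
  ev
}

#' Write an image as flat text (and optionally 32-bit float TIFF)
#'
#' The text file is the canonical exact-value output: comment headers record
#' the grid geometry, then the pixel matrix (rows = x index, columns = y
#' index) at full precision. If \code{tiff_path} is given, a 32-bit float
#' TIFF of the max-normalised image is written alongside, with the
#' normalisation factor recorded in both headers (the TIFF container stores
#' values in [0, 1]).
#'
#' @param image a \code{cc_image}.
#' @param path text output file.
#' @param tiff_path optional TIFF output file.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path, tiff_path = NULL) {
  g <- attr(image, "grid")
  scale <- max(unclass(image))
  hdr <- c(sprintf("# ccdew image: nx %d ny %d pixel_mm %.10g z %.10g center %.10g %.10g",
                   g$nx, g$ny, g$pixel_mm, g$z, g$center[1], g$center[2]),
           sprintf("# tiff_scale %.10g", scale))
  writeLines(hdr, path)
  write.table(format(unclass(image), digits = 17, scientific = TRUE,
                     trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  if (!is.null(tiff_path)) {
    m <- unclass(image)
    if (scale > 0) m <- m / scale
    tiff::writeTIFF(t(m), tiff_path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path text image file.
#' @return A \code{cc_image}.
#' @export
read_image <- function(path) {
  lines <- readLines(path, n = 2)
  h <- strsplit(sub("^# ccdew image: ", "", lines[1]), " ")[[1]]
  v <- as.numeric(h[c(2, 4, 6, 8, 10, 11)])
  g <- image_grid(nx = v[1], ny = v[2], pixel_mm = v[3], z = v[4],
                  center = v[5:6])
  m <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  new_cc_image(m, g)
}

# ------------------------------------------------------------- configuration

#' Default study configuration
#'
#' The fully serialisable configuration reproducing the reference simulation
#' study: two point sources (171 keV at (30, 0, 90) mm and 511 keV at
#' (-30, 0, 90) mm) in the 200 mm water cube, the four-layer Si/CdTe camera,
#' the three energy windows, the 200 x 200 px imaging plane at z = 90 mm and
#' 30 ML-EM iterations. Photon budgets default to a desk-scale run and are
#' meant to be overridden.
#'
#' @param n_photons_171,n_photons_511 photon budgets per source.
#' @param seed base seed; each source run derives its own stream from it.
#' @return A nested list of class \code{cc_config}.
#' @export
study_config <- function(n_photons_171 = 2e6, n_photons_511 = 2e7,
                         seed = 1) {
  structure(list(
    seed = seed,
    phantom = list(side_mm = 200, center = c(0, 0, 160), attenuation = TRUE),
    camera = list(active_mm = 32, scatterer_thickness_mm = 0.5,
                  absorber_thickness_mm = 0.75, layer_gap_mm = 4,
                  trigger_kev = 5),
    response = list(si_fwhm = 2.3, si_eref = 59.5, cdte_fwhm = 3.8,
                    cdte_eref = 81.0, resolution_model = "sqrt_scaling",
                    system_fwhm_target = 6.8, system_eref = 171,
                    calibrate = TRUE),
    sources = list(
      list(energy_kev = 171, position = c(30, 0, 90),
           n_photons = n_photons_171, emission_mode = "cone_biased",
           cone_half_angle_deg = 12, cone_fraction = 0.5),
      list(energy_kev = 511, position = c(-30, 0, 90),
           n_photons = n_photons_511, emission_mode = "cone_biased",
           cone_half_angle_deg = 12, cone_fraction = 0.5)),
    simulate = list(max_phantom_scatters = 3, force_detection = TRUE,
                    fluorescence_prob = 0),
    windows = list(photopeak = c(166, 176), scatter = c(176, 186),
                   photopeak_high = c(506, 516)),
    grid = list(nx = 200, ny = 200, pixel_mm = 1, z = 90, center = c(0, 0)),
    reconstruction = list(iterations = 30, arm_sigma_deg = NA,
                          arm_gamma_deg = NA, k = 1.0),
    rois = list(left = list(center = c(-30, 0), radius_mm = 15),
                right = list(center = c(30, 0), radius_mm = 15))),
    class = "cc_config")
}

#' Read / write a study configuration (YAML)
#'
#' @param config a \code{cc_config}.
#' @param path YAML file.
#' @return [read_study_config()] returns a \code{cc_config};
#'   [write_study_config()] returns \code{path} invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass(study_config())
  merged <- utils::modifyList(base, raw)
  # modifyList only merges named components; the per-source list is positional
  if (!is.null(raw$sources)) merged$sources <- raw$sources
  structure(merged, class = "cc_config")
}

# materialise configuration sections as package objects
.config_objects <- function(config) {
  ph <- config$phantom
  cm <- config$camera
  rs <- config$response
  list(
    phantom = phantom_spec(ph$side_mm, unlist(ph$center), ph$attenuation),
    camera = camera_geometry(cm$active_mm, cm$scatterer_thickness_mm,
                             cm$absorber_thickness_mm, cm$layer_gap_mm,
                             cm$trigger_kev),
    response = detector_response(rs$si_fwhm, rs$si_eref, rs$cdte_fwhm,
                                 rs$cdte_eref, rs$resolution_model,
                                 rs$system_fwhm_target, rs$system_eref,
                                 rs$calibrate),
    grid = do.call(image_grid, c(config$grid[c("nx", "ny", "pixel_mm", "z")],
                                 list(center = unlist(config$grid$center)))),
    sources = lapply(config$sources, function(s) {
      psi_deg <- s$cone_half_angle_deg %||% NA_real_
      source_spec(s$energy_kev, unlist(s$position), s$n_photons,
                  s$emission_mode,
                  cone_half_angle_rad = if (is.na(psi_deg)) NA_real_ else
                    psi_deg * pi / 180,
                  cone_fraction = s$cone_fraction %||% 1)
    }),
    windows = list(photopeak = energy_window(config$windows$photopeak[1],
                                             config$windows$photopeak[2],
                                             "photopeak"),
                   scatter = energy_window(config$windows$scatter[1],
                                           config$windows$scatter[2],
                                           "scatter")),
    rois = list(left = roi_spec(unlist(config$rois$left$center),
                                config$rois$left$radius_mm),
                right = roi_spec(unlist(config$rois$right$center),
                                 config$rois$right$radius_mm)))
}
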