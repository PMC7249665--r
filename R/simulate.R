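# Monte-Carlo generation of list-mode two-hit coincidence events.

# smallest cone (about the source-to-camera-centre axis) containing every
# corner of the detector stack, plus a 2-degree margin
.auto_cone_angle <- function(position, camera) {
  l <- camera$layers
  corners <- as.matrix(expand.grid(x = c(-1, 1) * l$xhalf[1],
                                   y = c(-1, 1) * l$yhalf[1],
                                   z = c(l$ztop, l$zbot)))
  axis <- -position / sqrt(sum(position^2))
  v <- sweep(corners, 2, position)
  v <- v / sqrt(rowSums(v^2))
  max(acos(pmin(1, v %*% axis))) + 2 * pi / 180
}

.listmode_cols <- c("event_id", "x1", "y1", "z1", "E1", "layer",
                    "x2", "y2", "z2", "E2", "weight", "truth_source_id",
                    "truth_primary_energy", "truth_n_phantom_scatters",
                    "truth_full_absorption", "truth_si_first")

.empty_events <- function() {
  tibble::tibble(event_id = integer(), x1 = numeric(), y1 = numeric(),
                 z1 = numeric(), E1 = numeric(), layer = integer(),
                 x2 = numeric(), y2 = numeric(), z2 = numeric(),
                 E2 = numeric(), weight = numeric(),
                 truth_source_id = character(),
                 truth_primary_energy = numeric(),
                 truth_n_phantom_scatters = integer(),
                 truth_full_absorption = logical(),
                 truth_si_first = logical())
}

#' Simulate list-mode Compton camera data
#'
#' Tracks primary photons from point sources through the water phantom
#' (free-path sampling against the total attenuation, photoelectric
#' absorption vs Klein-Nishina Compton scattering, up to
#' \code{max_phantom_scatters} orders) and through the four detector layers.
#' Events with energy deposits in the silicon scatterer and in exactly one
#' CdTe absorber layer, and in no other layer, are kept (the two-hit rule);
#' per-hit Gaussian energy blur and the trigger threshold are then applied.
#'
#' With \code{force_detection = TRUE} a variance-reduction daughter photon is
#' spawned at every phantom Compton vertex, aimed at a uniformly drawn point
#' on the scatterer face and weighted by the Klein-Nishina directional
#' density times the subtended solid angle (next-event estimation); analog
#' photons that scattered in the phantom are then dropped before the camera
#' so nothing is counted twice. Weighted tallies are unchanged in
#' expectation; only their variance improves.
#'
#' @param sources a [source_spec()] or list of them.
#' @param phantom a [phantom_spec()].
#' @param camera a [camera_geometry()].
#' @param response a [detector_response()].
#' @param seed integer seed for the run (required; all randomness flows from
#'   it through the R random number stream).
#' @param max_phantom_scatters photons are terminated after this many Compton
#'   scatters in the phantom (default 3; higher orders contribute negligibly
#'   to the energy windows studied).
#' @param force_detection spawn forced-detection daughters (see Details).
#' @param fluorescence_prob probability that a photoelectric absorption in
#'   the top CdTe layer sends a Cd/Te K-alpha photon (23.2 or 27.5 keV,
#'   equal odds) into the silicon layer — the event class targeted by the
#'   fluorescence veto. Off (0) by default.
#' @param blur apply the detector energy blur (disable for kinematic tests).
#' @param quiet suppress the per-source bookkeeping message.
#' @return A tibble of list-mode events: scatterer hit (\code{x1, y1, z1,
#'   E1}), absorber layer (1-3) and hit (\code{x2, y2, z2, E2}), importance
#'   \code{weight}, and truth fields (source id, primary energy, number of
#'   phantom scatters, full-absorption flag, and whether the silicon
#'   interaction came first — events where the photon hit a CdTe layer first
#'   and backscattered into the silicon are kept, as a real camera cannot
#'   order the hits, but their cone angles are genuinely wrong). Counter totals are attached as
#'   attribute \code{"counters"}.
#' @export
simulate_camera <- function(sources, phantom = phantom_spec(),
                            camera = camera_geometry(),
                            response = detector_response(), seed,
                            max_phantom_scatters = 3, force_detection = FALSE,
                            fluorescence_prob = 0, blur = TRUE,
                            quiet = FALSE) {
  if (inherits(sources, "cc_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1, inherits(phantom, "cc_phantom"),
            inherits(camera, "cc_camera"), inherits(response, "cc_response"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))

  half <- phantom$side_mm / 2
  lo <- phantom$center - half
  hi <- phantom$center + half
  layers <- .layer_matrix(camera)
  tw <- .att_matrix("water")
  tsi <- .att_matrix("silicon")
  tcd <- .att_matrix("cadmium_telluride")
  rex <- if (response$resolution_model == "sqrt_scaling") 0.5 else 0

  out <- vector("list", length(sources))
  counters <- list()
  for (is in seq_along(sources)) {
    src <- sources[[is]]
    stopifnot(inherits(src, "cc_source"))
    if (phantom$attenuation &&
        (any(src$position < lo) || any(src$position > hi))) {
      stop("source position must lie inside the phantom")
    }
    if (src$position[3] <= max(camera$layers$ztop)) {
      warning("source at or below the camera plane: zero geometric acceptance")
    }
    axis <- -src$position
    psi <- src$cone_half_angle_rad
    if (is.na(psi)) psi <- .auto_cone_angle(src$position, camera)
    res <- cpp_simulate(
      n_photons = src$n_photons, E0 = src$energy_kev, src = src$position,
      emission_mode = if (src$emission_mode == "cone_biased") 1L else 0L,
      cone_axis = axis, cone_half_angle = psi,
      cone_fraction = src$cone_fraction,
      cube_center = phantom$center, cube_half = half,
      attenuate = phantom$attenuation, layers = layers,
      tab_water = tw, tab_si = tsi, tab_cdte = tcd,
      si_fwhm = response$si_fwhm, si_eref = response$si_eref,
      cdte_fwhm = response$cdte_fwhm, cdte_eref = response$cdte_eref,
      blur_scale = response$blur_scale, res_exponent = rex, blur = blur,
      trigger_kev = camera$trigger_kev,
      max_scatters = as.integer(max_phantom_scatters),
      force_detection = force_detection, fluor_prob = fluorescence_prob)
    m <- res$events
    ev <- if (nrow(m) == 0) .empty_events() else tibble::tibble(
      event_id = 0L, x1 = m[, 1], y1 = m[, 2], z1 = m[, 3], E1 = m[, 4],
      layer = as.integer(m[, 5]), x2 = m[, 6], y2 = m[, 7], z2 = m[, 8],
      E2 = m[, 9], weight = m[, 10], truth_source_id = src$label,
      truth_primary_energy = m[, 11],
      truth_n_phantom_scatters = as.integer(m[, 12]),
      truth_full_absorption = m[, 13] > 0.5,
      truth_si_first = m[, 14] > 0.5)
    counters[[src$label]] <- res[c("n_generated", "n_twohit", "n_recorded",
                                   "n_daughters", "n_daughter_events")]
    if (!quiet) {
      message(sprintf(
        "source %s: %.0f primaries -> %.0f two-hit, %.0f recorded (%.0f from forced daughters)",
        src$label, res$n_generated, res$n_twohit, res$n_recorded,
        res$n_daughter_events))
    }
    if (nrow(ev) == 0 && !phantom$attenuation) {
      warning(sprintf("source %s produced no events", src$label))
    }
    out[[is]] <- ev
  }
  ev <- do.call(rbind, out)
  ev$event_id <- seq_len(nrow(ev))
  attr(ev, "counters") <- counters
  ev
}

#' Summed-energy spectrum of list-mode events
#'
#' Weighted histogram of E1 + E2, the quantity the energy windows act on.
#'
#' @param events list-mode events tibble.
#' @param bin_width histogram bin width, keV (> 0).
#' @param range length-2 numeric, keV; bins cover \code{[range[1], range[2])}.
#' @return A tibble with \code{lower}, \code{upper}, \code{mid} (keV) and the
#'   weighted \code{count} per bin. The counts sum to the total weight of
#'   in-range events.
#' @export
energy_spectrum <- function(events, bin_width = 1, range = c(0, 600)) {
  stopifnot(bin_width > 0, length(range) == 2, range[1] < range[2])
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  n <- length(edges) - 1
  counts <- numeric(n)
  if (nrow(events) > 0) {
    etot <- events$E1 + events$E2
    idx <- findInterval(etot, edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= n
    if (any(ok)) {
      agg <- tapply(events$weight[ok], idx[ok], sum)
      counts[as.integer(names(agg))] <- agg
    }
  }
  tibble::tibble(lower = edges[-length(edges)], upper = edges[-1],
                 mid = (edges[-length(edges)] + edges[-1]) / 2,
                 count = counts)
}
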