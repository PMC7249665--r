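# Event selection: energy windows, fluorescence veto, unphysical-event drop.
# All filters are pure (input untouched, order preserved), idempotent, and
# commute with one another.

#' Select events by summed-energy window
#'
#' Keeps events whose total deposited energy E1 + E2 lies inside the closed
#' window \code{[lo, hi]} (both bounds inclusive).
#'
#' @param events list-mode events tibble.
#' @param window an [energy_window()].
#' @return The filtered events, order preserved.
#' @export
select_window <- function(events, window) {
  stopifnot(inherits(window, "cc_window"))
  etot <- events$E1 + events$E2
  events[etot >= window$lo & etot <= window$hi, , drop = FALSE]
}

#' Veto fluorescence-like coincidences
#'
#' Removes events that deposited 20-35 keV in the silicon scatterer with the
#' absorber hit in the top CdTe layer: this signature is typical of Cd/Te
#' characteristic X-rays escaping the first absorber, not of a Compton
#' scatter, and would otherwise corrupt the cone angles.
#'
#' @param events list-mode events tibble.
#' @param band inclusive silicon-energy band of the veto, keV.
#' @param layer absorber layer index the veto applies to (1 = top CdTe).
#' @return The filtered events, order preserved.
#' @export
reject_fluorescence <- function(events, band = c(20, 35), layer = 1L) {
  drop <- events$E1 >= band[1] & events$E1 <= band[2] & events$layer == layer
  events[!drop, , drop = FALSE]
}

#' Drop kinematically impossible events
#'
#' Removes events whose (E1, E2) pair has no real Compton scattering angle
#' (the cosine from the scattering kinematics falls outside [-1, 1], which
#' can happen after energy blur). The number of dropped events is reported
#' with a message unless \code{quiet}.
#'
#' @param events list-mode events tibble.
#' @param quiet suppress the dropped-count message.
#' @return The filtered events, order preserved.
#' @export
drop_unphysical <- function(events, quiet = FALSE) {
  if (nrow(events) == 0) return(events)
  th <- scatter_angle_from_energies(events$E1, events$E2)
  n_drop <- sum(is.na(th))
  if (!quiet && n_drop > 0) {
    message(sprintf("drop_unphysical: removed %d of %d events", n_drop,
                    nrow(events)))
  }
  events[!is.na(th), , drop = FALSE]
}

#' Standard selection pipeline
#'
#' Fluorescence veto, then unphysical-event drop, then the energy window —
#' the fixed order used throughout the package (the veto and the window act
#' on independent quantities and commute; the order only fixes the logs).
#'
#' @param events list-mode events tibble.
#' @param window an [energy_window()], or \code{NULL} to skip the window cut.
#' @param quiet suppress messages.
#' @return The filtered events.
#' @export
select_events <- function(events, window = NULL, quiet = FALSE) {
  ev <- reject_fluorescence(events)
  ev <- drop_unphysical(ev, quiet = quiet)
  if (!is.null(window)) ev <- select_window(ev, window)
  ev
}
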