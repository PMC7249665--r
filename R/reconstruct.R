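# Image formation: Voigt ARM kernel, cone residuals, ARM calibration,
# cone-surface backprojection and list-mode ML-EM on a planar grid.

new_cc_image <- function(values, grid) {
  stopifnot(is.matrix(values), nrow(values) == grid$nx, ncol(values) == grid$ny)
  structure(values, grid = grid, class = c("cc_image", "matrix", "array"))
}

#' @export
print.cc_image <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<cc_image> %d x %d px (%.3g mm/px), plane z = %.6g mm\n",
              g$nx, g$ny, g$pixel_mm, g$z))
  cat(sprintf("  values: min %.6g, max %.6g, sum %.6g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' Grid of an image
#' @param image a \code{cc_image}.
#' @return The [image_grid()] the image lives on.
#' @export
image_grid_of <- function(image) attr(image, "grid")

# events -> apex / axis / theta arrays used by the C++ kernels
.event_cones <- function(events) {
  if (nrow(events) == 0) {
    return(list(apex = matrix(0, 0, 3), axis = matrix(0, 0, 3),
                theta = numeric(0), w = numeric(0)))
  }
  theta <- scatter_angle_from_energies(events$E1, events$E2)
  if (anyNA(theta)) {
    stop("events contain kinematically impossible (E1, E2) pairs; ",
         "apply drop_unphysical() first")
  }
  ax <- cbind(events$x1 - events$x2, events$y1 - events$y2,
              events$z1 - events$z2)
  nn <- sqrt(rowSums(ax^2))
  if (any(nn == 0)) stop("degenerate event with coincident hit positions")
  list(apex = cbind(events$x1, events$y1, events$z1), axis = ax / nn,
       theta = theta, w = events$weight)
}

#' Signed angular residual of a point from an event's Compton cone
#'
#' For one event, the cone of possible incidence directions has its apex at
#' the scatterer hit, its axis along the absorber-to-scatterer direction
#' (extended toward the source side), and half-angle theta from the energy
#' pair. The residual at a reference point is \code{beta - theta}, where
#' beta is the angle between the cone axis and the apex-to-point vector:
#' zero exactly on the cone surface, \code{-theta} on the axis.
#'
#' @param event a single-row list-mode events tibble.
#' @param point numeric length-3, or an n x 3 matrix of points (mm).
#' @return Signed residual(s) in rad.
#' @export
cone_angular_residual <- function(event, point) {
  stopifnot(nrow(event) == 1)
  cones <- .event_cones(event)
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  stopifnot(ncol(pts) == 3)
  if (any(rowSums((pts - matrix(cones$apex, nrow(pts), 3, byrow = TRUE))^2) == 0)) {
    stop("reference point coincides with the cone apex")
  }
  cpp_residuals_event(cones$apex[1, ], cones$axis[1, ], cones$theta, pts)
}

#' Voigt profile density
#'
#' Convolution of a Gaussian (sigma) and a Lorentzian (half-width gamma),
#' evaluated through the Faddeeva function and normalised to unit integral
#' over the real line. This is the angular response (ARM) kernel of the
#' camera: both reconstruction algorithms spread each event's cone by it.
#'
#' @param x evaluation points, rad; vectorised.
#' @param params a [voigt_params()].
#' @return Density per rad.
#' @export
voigt_profile <- function(x, params) {
  stopifnot(inherits(params, "cc_voigt"))
  cpp_voigt(as.numeric(x), params$sigma, params$gamma)
}

#' Calibrate the ARM kernel from a known point source
#'
#' Histograms the cone angular residuals of the events at the true source
#' position and fits amplitude x Voigt(sigma, gamma) + flat floor by
#' nonlinear least squares. This is the "point source imaging examination"
#' that fixes the reconstruction kernel.
#'
#' @param events list-mode events from a point source (>= 500 recommended),
#'   already selected (no unphysical events).
#' @param true_position the source position, mm (length-3).
#' @param fit_range_deg residuals within +- this range enter the fit (deg).
#' @param bin_deg histogram bin width (deg).
#' @return A [voigt_params()] with the fit object attached as attribute
#'   \code{"fit"} (coefficients in rad).
#' @export
calibrate_arm <- function(events, true_position, fit_range_deg = 15,
                          bin_deg = 0.25) {
  cones <- .event_cones(events)
  if (length(cones$theta) < 10) stop("too few events for an ARM fit")
  r <- cpp_residuals_point(cones$apex, cones$axis, cones$theta,
                           as.numeric(true_position))
  rr <- fit_range_deg * pi / 180
  bw <- bin_deg * pi / 180
  edges <- seq(-rr, rr, by = bw)
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= length(edges) - 1
  dens <- numeric(length(edges) - 1)
  agg <- tapply(cones$w[ok], idx[ok], sum)
  dens[as.integer(names(agg))] <- agg / (sum(cones$w[ok]) * bw)
  mid <- (edges[-1] + edges[-length(edges)]) / 2

  floor0 <- max(median(dens[abs(mid) > 0.8 * rr]), 1e-12)
  peak <- max(dens)
  half <- dens >= floor0 + (peak - floor0) / 2
  fwhm0 <- max(diff(range(mid[half])), 2 * bw)
  start <- c(amp = (peak - floor0) * fwhm0 * 1.5,
             sigma = fwhm0 / 2.3548, gamma = fwhm0 / 4, floor = floor0)
  resid_fn <- function(p) {
    dens - (p[1] * cpp_voigt(mid, p[2], p[3]) + p[4])
  }
  fit <- minpack.lm::nls.lm(par = start, lower = rep(0, 4), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4 || (fit$par[2] == 0 && fit$par[3] == 0)) {
    stop("ARM fit failed: ", fit$message, " (", length(r), " events, ",
         "info ", fit$info, ")")
  }
  params <- voigt_params(unname(fit$par[2]), unname(fit$par[3]))
  attr(params, "fit") <- list(par = setNames(fit$par, names(start)),
                              info = fit$info, message = fit$message,
                              histogram = tibble::tibble(mid = mid,
                                                         density = dens))
  params
}

#' Cone-surface backprojection with the Voigt kernel
#'
#' Forms the image \eqn{\lambda_j = \sum_i w_i V(\theta_{ij}; \sigma,
#' \gamma)}, where \eqn{\theta_{ij}} is the angular residual of pixel j from
#' event i's cone: every event paints its cone-plane intersection, spread by
#' the ARM kernel.
#'
#' @param events selected list-mode events.
#' @param grid an [image_grid()].
#' @param params a [voigt_params()].
#' @param cutoff optional angular truncation of the kernel, rad; by default
#'   no truncation (every pixel receives every event's kernel value).
#' @return A \code{cc_image}.
#' @export
backproject <- function(events, grid, params, cutoff = Inf) {
  stopifnot(inherits(grid, "cc_grid"), inherits(params, "cc_voigt"))
  cones <- .event_cones(events)
  img <- cpp_backproject(cones$apex, cones$axis, cones$theta, cones$w,
                         grid$xs, grid$ys, grid$z, params$sigma,
                         params$gamma, cutoff)
  new_cc_image(img, grid)
}

#' List-mode ML-EM reconstruction
#'
#' Iterates the list-mode maximum-likelihood expectation-maximisation update
#' \deqn{\lambda_j^{(k+1)} = \frac{\lambda_j^{(k)}}{S_j} \sum_i
#'   \frac{w_i t_{ij}}{\sum_m t_{im} \lambda_m^{(k)}},}
#' with transition probabilities \eqn{t_{ij} = V(\theta_{ij}; \sigma,
#' \gamma)} — the same Voigt cone kernel as [backproject()] — and detection
#' efficiency \eqn{S_j} (uniform by default; see [estimate_sensitivity()]).
#' Nonnegativity and exact zeros of the initial image are preserved. Events
#' whose cones miss the field of view entirely (zero forward projection) are
#' excluded with a count, not an error.
#'
#' @param events selected list-mode events.
#' @param grid an [image_grid()].
#' @param params a [voigt_params()].
#' @param sensitivity a \code{cc_image} or matrix of strictly positive
#'   per-pixel efficiencies; \code{NULL} for uniform.
#' @param iterations number of update passes (default 30, the reference
#'   study's setting); 0 returns \code{init} unchanged.
#' @param init initial image (\code{cc_image} or matrix, nonnegative);
#'   \code{NULL} for uniform ones.
#' @param cutoff optional angular truncation of the kernel, rad (default:
#'   none).
#' @param cache_bytes per-event kernel rows are cached when they fit within
#'   this budget (bytes), else recomputed every iteration; results are
#'   identical either way.
#' @return A \code{cc_image} with attributes \code{"loglik"} (the list-mode
#'   log-likelihood \eqn{\sum_i w_i \log \sum_m t_{im}\lambda_m} after each
#'   update; non-decreasing) and \code{"n_excluded"}.
#' @export
mlem <- function(events, grid, params, sensitivity = NULL, iterations = 30,
                 init = NULL, cutoff = Inf, cache_bytes = 8e8) {
  stopifnot(inherits(grid, "cc_grid"), inherits(params, "cc_voigt"),
            iterations >= 0)
  npix <- grid$nx * grid$ny
  sens <- if (is.null(sensitivity)) rep(1, npix) else as.numeric(sensitivity)
  if (length(sens) != npix || any(sens <= 0)) {
    stop("`sensitivity` must be strictly positive on the full grid")
  }
  init_m <- if (is.null(init)) matrix(1, grid$nx, grid$ny) else {
    stopifnot(nrow(init) == grid$nx, ncol(init) == grid$ny, all(init >= 0))
    unclass(init)
  }
  if (iterations == 0) {
    out <- new_cc_image(init_m, grid)
    attr(out, "loglik") <- numeric(0)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  cones <- .event_cones(events)
  res <- cpp_mlem(cones$apex, cones$axis, cones$theta, cones$w,
                  grid$xs, grid$ys, grid$z, params$sigma, params$gamma,
                  sens, as.numeric(init_m), as.integer(iterations), cutoff,
                  cache_bytes)
  out <- new_cc_image(res$image, grid)
  attr(out, "loglik") <- res$loglik
  attr(out, "n_excluded") <- res$n_excluded
  if (res$n_excluded > 0) {
    message(sprintf("mlem: %d event(s) with empty forward projection excluded",
                    res$n_excluded))
  }
  out
}

#' Monte-Carlo sensitivity map
#'
#' Optional alternative to the uniform default: simulates a point source at
#' each node of a coarse subgrid of the imaging plane, counts selected
#' events per emitted photon, and bilinearly upsamples to the full grid.
#' For the reference geometry (200 mm plane, 90 mm from a 32 mm camera) the
#' efficiency varies slowly, which is why uniform is the default.
#'
#' @param grid an [image_grid()].
#' @param window an [energy_window()] the sensitivity refers to.
#' @param source_energy photon energy of the mapped isotope, keV.
#' @param phantom,camera,response scene objects as in [simulate_camera()].
#' @param n_sub nodes per axis of the coarse subgrid.
#' @param n_photons primaries per node.
#' @param seed integer seed.
#' @return A \code{cc_image} of relative efficiencies, scaled to mean 1 and
#'   floored at a small positive value (division-safe).
#' @export
estimate_sensitivity <- function(grid, window, source_energy = 171,
                                 phantom = phantom_spec(),
                                 camera = camera_geometry(),
                                 response = detector_response(),
                                 n_sub = 5, n_photons = 2e5, seed = 1) {
  xs <- seq(min(grid$xs), max(grid$xs), length.out = n_sub)
  ys <- seq(min(grid$ys), max(grid$ys), length.out = n_sub)
  coarse <- matrix(0, n_sub, n_sub)
  for (i in seq_len(n_sub)) {
    for (j in seq_len(n_sub)) {
      src <- source_spec(source_energy, c(xs[i], ys[j], grid$z), n_photons,
                         emission_mode = "cone_biased", cone_fraction = 1)
      ev <- simulate_camera(src, phantom, camera, response,
                            seed = seed + 1000L * i + j, quiet = TRUE)
      ev <- select_events(ev, window, quiet = TRUE)
      coarse[i, j] <- sum(ev$weight) / n_photons
    }
  }
  fx <- approx(xs, seq_len(n_sub), xout = grid$xs, rule = 2)$y
  fy <- approx(ys, seq_len(n_sub), xout = grid$ys, rule = 2)$y
  up <- matrix(0, grid$nx, grid$ny)
  for (j in seq_len(grid$ny)) {
    j0 <- pmin(floor(fy[j]), n_sub - 1); tj <- fy[j] - j0
    col <- coarse[, j0] * (1 - tj) + coarse[, j0 + 1] * tj
    i0 <- pmin(floor(fx), n_sub - 1); ti <- fx - i0
    up[, j] <- col[i0] * (1 - ti) + col[i0 + 1] * ti
  }
  up <- up / mean(up)
  up[up < 1e-6] <- 1e-6
  new_cc_image(up, grid)
}

#' Extract a 1-D profile from an image
#'
#' Pixel row (or column) through a stated coordinate, e.g. the x-profile at
#' y = 0 used to compare point-spread widths.
#'
#' @param image a \code{cc_image}.
#' @param axis \code{"x"} (profile along x at fixed y) or \code{"y"}.
#' @param coordinate the fixed coordinate, mm; snapped to the nearest pixel
#'   centre when within half a pixel (so y = 0 picks the row at -0.5 mm on
#'   the default even-sized grid), an error beyond that.
#' @param normalize divide by the profile maximum.
#' @return A tibble with \code{position} (mm) and \code{value}.
#' @export
image_profile <- function(image, axis = c("x", "y"), coordinate = 0,
                          normalize = FALSE) {
  axis <- match.arg(axis)
  g <- attr(image, "grid")
  snap <- function(centres) {
    i <- which.min(abs(centres - coordinate))
    if (abs(centres[i] - coordinate) > g$pixel_mm / 2 + 1e-9) {
      stop("`coordinate` is outside the grid")
    }
    i
  }
  if (axis == "x") {
    out <- tibble::tibble(position = g$xs,
                          value = unclass(image)[, snap(g$ys)])
  } else {
    out <- tibble::tibble(position = g$ys,
                          value = unclass(image)[snap(g$xs), ])
  }
  if (normalize) out$value <- out$value / max(out$value)
  out
}

#' Location of the image maximum
#'
#' @param image a \code{cc_image}.
#' @return Length-2 numeric (x, y) of the maximal pixel centre, mm; ties are
#'   broken toward the lowest linear pixel index.
#' @export
image_argmax <- function(image) {
  g <- attr(image, "grid")
  k <- which.max(unclass(image)) # first maximum in column-major order
  ix <- (k - 1) %% g$nx + 1
  iy <- (k - 1) %/% g$nx + 1
  c(x = g$xs[ix], y = g$ys[iy])
}

#' Full width at half maximum of a profile
#'
#' Linear-interpolated width at half of the profile maximum.
#'
#' @param profile a tibble from [image_profile()].
#' @return FWHM in the profile's position units.
#' @export
profile_fwhm <- function(profile) {
  x <- profile$position
  y <- profile$value
  k <- which.max(y)
  half <- y[k] / 2
  left <- NA_real_
  for (i in seq_len(k - 1)) {
    if (y[i] <= half && y[i + 1] > half) {
      left <- x[i] + (x[i + 1] - x[i]) * (half - y[i]) / (y[i + 1] - y[i])
    }
  }
  right <- NA_real_
  for (i in seq(length(y) - 1, k, by = -1)) {
    if (y[i + 1] <= half && y[i] > half) {
      right <- x[i] + (x[i + 1] - x[i]) * (y[i] - half) / (y[i] - y[i + 1])
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("profile does not cross half maximum on both sides")
  }
  right - left
}
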