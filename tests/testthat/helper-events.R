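# Shared fixtures: hand-built list-mode tables and exact synthetic cone events.

# minimal valid list-mode tibble from energy pairs (kinematics not implied)
make_events <- function(E1, E2, layer = 2L, weight = 1,
                        x1 = 0, y1 = 0, z1 = 0,
                        x2 = 0, y2 = 0, z2 = -4.5) {
  n <- max(length(E1), length(E2))
  tibble::tibble(
    event_id = seq_len(n),
    x1 = rep_len(x1, n), y1 = rep_len(y1, n), z1 = rep_len(z1, n),
    E1 = rep_len(E1, n), layer = rep_len(as.integer(layer), n),
    x2 = rep_len(x2, n), y2 = rep_len(y2, n), z2 = rep_len(z2, n),
    E2 = rep_len(E2, n), weight = rep_len(weight, n),
    truth_source_id = "fixture", truth_primary_energy = NA_real_,
    truth_n_phantom_scatters = NA_integer_, truth_full_absorption = NA,
    truth_si_first = NA)
}

# rotate unit vector d by polar angle theta (about d) with azimuth phi;
# independent R reimplementation used to build exact geometric fixtures
rotate_dir <- function(d, theta, phi) {
  if (abs(d[3]) < 0.999) u <- c(-d[2], d[1], 0) else u <- c(0, -d[3], d[2])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  sin(theta) * (cos(phi) * u + sin(phi) * v) + cos(theta) * d
}

# exact noiseless two-hit events whose Compton cones pass through `point`
# (up to an angular perturbation `err` applied to the absorber direction):
# the residual of event i at `point` is exactly err[i].
make_cone_events <- function(point, theta, err = 0, phi = NULL, E0 = 171,
                             apex = NULL) {
  n <- length(theta)
  err <- rep_len(err, n)
  if (is.null(phi)) phi <- runif(n, 0, 2 * pi)
  if (is.null(apex)) {
    apex <- cbind(runif(n, -14, 14), runif(n, -14, 14), runif(n, -0.2, 0.2))
  }
  E2 <- scattered_energy(E0, theta)
  E1 <- E0 - E2
  x2 <- y2 <- z2 <- numeric(n)
  for (i in seq_len(n)) {
    d_in <- apex[i, ] - point
    d_in <- d_in / sqrt(sum(d_in^2))
    d_out <- rotate_dir(d_in, theta[i] + err[i], phi[i])
    hit2 <- apex[i, ] + 6 * d_out
    x2[i] <- hit2[1]; y2[i] <- hit2[2]; z2[i] <- hit2[3]
  }
  tibble::tibble(
    event_id = seq_len(n),
    x1 = apex[, 1], y1 = apex[, 2], z1 = apex[, 3],
    E1 = E1, layer = 2L, x2 = x2, y2 = y2, z2 = z2, E2 = E2,
    weight = 1, truth_source_id = "synthetic",
    truth_primary_energy = E0, truth_n_phantom_scatters = 0L,
    truth_full_absorption = TRUE, truth_si_first = TRUE)
}

# small cached clean point-source dataset shared by reconstruction tests
clean_pointsource_events <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      src <- source_spec(171, c(30, 0, 90), 6e6,
                         emission_mode = "cone_biased", cone_fraction = 1)
      ev <- simulate_camera(src, seed = 5, quiet = TRUE)
      cache <<- select_events(ev, window_photopeak_171(), quiet = TRUE)
    }
    cache
  }
})

# pixel values of an image without its class/attribute baggage
img_values <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}
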