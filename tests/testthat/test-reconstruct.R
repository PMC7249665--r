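# Voigt kernel, cone residuals, ARM calibration, backprojection and ML-EM.

test_that("cone residual vanishes on the cone and is -theta on the axis", {
  set.seed(3)
  P <- c(30, 0, 90)
  ev <- make_cone_events(P, theta = c(0.3, 0.7, 1.1, 1.9))
  for (i in seq_len(nrow(ev))) {
    expect_equal(cone_angular_residual(ev[i, ], P), 0, tolerance = 1e-9)
    # a point on the source-side cone axis: beta = 0, residual = -theta
    apex <- c(ev$x1[i], ev$y1[i], ev$z1[i])
    axis <- apex - c(ev$x2[i], ev$y2[i], ev$z2[i])
    axis <- axis / sqrt(sum(axis^2))
    on_axis <- apex + 50 * axis
    th <- scatter_angle_from_energies(ev$E1[i], ev$E2[i])
    # acos is ill-conditioned where the point lies exactly on the axis
    expect_equal(cone_angular_residual(ev[i, ], on_axis), -th,
                 tolerance = 1e-7)
  }
  expect_error(cone_angular_residual(ev[1, ],
                                     c(ev$x1[1], ev$y1[1], ev$z1[1])),
               "apex")
})

test_that("simulated noiseless events have zero residual at the source", {
  ev <- simulate_camera(
    source_spec(171, c(30, 0, 90), 1.2e6, emission_mode = "cone_biased"),
    phantom_spec(attenuation = FALSE), seed = 13, blur = FALSE, quiet = TRUE)
  fa <- ev[ev$truth_full_absorption & ev$truth_si_first, ]
  fa <- fa[seq_len(min(1000, nrow(fa))), ]
  expect_gte(nrow(fa), 500)
  cones <- ccdew:::.event_cones(fa)
  r <- ccdew:::cpp_residuals_point(cones$apex, cones$axis, cones$theta,
                                   c(30, 0, 90))
  expect_lt(max(abs(r)), 1e-9)
})

test_that("Voigt profile has the right limits and unit normalisation", {
  s <- 2 * pi / 180
  # gamma = 0: Gaussian peak value
  expect_equal(voigt_profile(0, voigt_params(s, 0)), 1 / (s * sqrt(2 * pi)),
               tolerance = 1e-6)
  expect_equal(voigt_profile(c(-s, s), voigt_params(s, 0)),
               rep(dnorm(s, 0, s), 2), tolerance = 1e-12)
  # sigma -> 0: Lorentzian density
  g <- 0.01
  expect_equal(voigt_profile(0.02, voigt_params(1e-9, g)),
               g / (pi * (0.02^2 + g^2)), tolerance = 1e-5)
  expect_equal(voigt_profile(0.02, voigt_params(0, g)),
               g / (pi * (0.02^2 + g^2)), tolerance = 1e-12)
  # unit integral over the real line
  vp <- voigt_params(s, s)
  f <- function(x) voigt_profile(x, vp)
  q <- integrate(f, -Inf, 0)$value + integrate(f, 0, Inf)$value
  expect_equal(q, 1, tolerance = 1e-4)
  # the (-pi, pi) integral is short of 1 by the Lorentzian tail mass
  q2 <- integrate(f, 0, pi)$value * 2
  expect_equal(q2, 0.99293, tolerance = 1e-4)
  # agreement with direct Gaussian * Lorentzian convolution quadrature
  conv <- function(x) {
    integrate(function(t) dnorm(t, 0, vp$sigma) * dcauchy(x - t, 0, vp$gamma),
              -Inf, Inf, rel.tol = 1e-12)$value
  }
  xs <- c(0, 0.01, 0.05, 0.2, 1)
  expect_equal(voigt_profile(xs, vp), vapply(xs, conv, numeric(1)),
               tolerance = 1e-5)
  expect_error(voigt_params(0, 0), "both")
})

test_that("ARM calibration recovers known kernel parameters", {
  P <- c(30, 0, 90)
  deg <- pi / 180
  set.seed(71)
  # pure Gaussian residuals, sigma* = 1 degree
  ev <- make_cone_events(P, theta = runif(4000, 0.35, 1.2),
                         err = rnorm(4000, 0, deg))
  fit <- calibrate_arm(ev, P)
  expect_lt(abs(fit$sigma - deg) / deg, 0.15)
  expect_lt(fit$gamma, 0.35 * deg)
  # pure Lorentzian residuals, gamma* = 1 degree (mirror image)
  set.seed(72)
  ev <- make_cone_events(P, theta = runif(4000, 0.35, 1.2),
                         err = rcauchy(4000, 0, deg))
  fit <- calibrate_arm(ev, P)
  expect_lt(abs(fit$gamma - deg) / deg, 0.2)
  expect_lt(fit$sigma, 0.35 * deg)
  # more events -> smaller recovery error (averaged over replicates)
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(sd) {
      set.seed(sd)
      e <- make_cone_events(P, theta = runif(n, 0.35, 1.2),
                            err = rnorm(n, 0, deg))
      abs(calibrate_arm(e, P)$sigma - deg)
    }, numeric(1)))
  }
  expect_lt(err_at(6000, 81:85), err_at(400, 81:85))
})

test_that("backprojection paints cones with the Voigt kernel peak", {
  grid <- image_grid()
  vp <- voigt_params(1.2 * pi / 180, 0.3 * pi / 180)
  set.seed(4)
  # single noiseless event whose cone passes through the pixel centre (30.5, 0.5)
  ev <- make_cone_events(c(30.5, 0.5, 90), theta = 0.8)
  ev$weight <- 2.5
  img <- backproject(ev, grid, vp)
  expect_equal(max(img), 2.5 * voigt_profile(0, vp), tolerance = 1e-9)
  expect_true(all(img >= 0))
  # empty event list -> zero image
  img0 <- backproject(ev[0, ], grid, vp)
  expect_true(all(unclass(img0) == 0))
  # linearity over event concatenation
  a <- make_cone_events(c(30.5, 0.5, 90), theta = runif(5, 0.4, 1.0))
  b <- make_cone_events(c(-29.5, 0.5, 90), theta = runif(4, 0.4, 1.0))
  expect_equal(img_values(backproject(merge_listmode(a, b), grid, vp)),
               img_values(backproject(a, grid, vp)) +
                 img_values(backproject(b, grid, vp)),
               tolerance = 1e-12)
  # permutation invariance
  perm <- sample(nrow(a))
  expect_equal(img_values(backproject(a[perm, ], grid, vp)),
               img_values(backproject(a, grid, vp)), tolerance = 1e-12)
})

test_that("point-source data reconstruct at the true position", {
  sel <- clean_pointsource_events()
  expect_gt(nrow(sel), 1000)
  arm <- calibrate_arm(sel, c(30, 0, 90))
  grid <- image_grid()
  bp <- backproject(sel, grid, arm)
  expect_lt(sqrt(sum((image_argmax(bp) - c(30, 0))^2)), 2)
})

test_that("ML-EM iterates the multiplicative update correctly", {
  grid <- image_grid(nx = 60, ny = 60, pixel_mm = 1, z = 90,
                     center = c(30, 0))
  vp <- voigt_params(1.2 * pi / 180, 0.3 * pi / 180)
  set.seed(6)
  ev <- make_cone_events(c(30.5, 0.5, 90), theta = runif(120, 0.4, 1.1))
  # iterations = 0 returns the initial image unchanged
  init <- matrix(runif(3600, 0.5, 2), 60, 60)
  out0 <- mlem(ev, grid, vp, iterations = 0, init = init)
  expect_equal(img_values(out0), init)
  # log-likelihood is non-decreasing; mass equals total weight
  out <- mlem(ev, grid, vp, iterations = 20)
  ll <- attr(out, "loglik")
  expect_length(ll, 20)
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-1])))
  expect_equal(sum(out), sum(ev$weight), tolerance = 1e-9)
  # concentrates at the source
  expect_lt(sqrt(sum((image_argmax(out) - c(30, 0))^2)), 2)
  # nonnegativity and zero preservation
  init2 <- matrix(1, 60, 60)
  init2[1:10, ] <- 0
  out2 <- mlem(ev, grid, vp, iterations = 5, init = init2)
  expect_true(all(unclass(out2) >= 0))
  expect_true(all(unclass(out2)[1:10, ] == 0))
  # permutation invariance up to floating tolerance
  perm <- sample(nrow(ev))
  outp <- mlem(ev[perm, ], grid, vp, iterations = 5)
  expect_equal(img_values(outp), img_values(mlem(ev, grid, vp, iterations = 5)),
               tolerance = 1e-10)
  # cached and uncached kernel paths agree exactly
  out_nc <- mlem(ev, grid, vp, iterations = 5, cache_bytes = 0)
  expect_equal(img_values(out_nc), img_values(mlem(ev, grid, vp, iterations = 5)),
               tolerance = 1e-12)
})

test_that("degenerate single-pixel grid is a fixed point at matched mass", {
  grid <- image_grid(nx = 1, ny = 1, pixel_mm = 1, z = 90, center = c(30, 0))
  vp <- voigt_params(0.02, 0.005)
  set.seed(9)
  ev <- make_cone_events(c(30, 0, 90), theta = runif(8, 0.4, 1.0))
  init <- matrix(sum(ev$weight), 1, 1) # t_ij constant over j: mass-matched
  out <- mlem(ev, grid, vp, iterations = 7, init = init)
  expect_equal(img_values(out), init, tolerance = 1e-12)
})

test_that("profiles extract rows with optional normalisation", {
  grid <- image_grid(nx = 20, ny = 20, pixel_mm = 1, z = 90)
  m <- matrix(0, 20, 20)
  m[7, 12] <- 3 # delta image
  img <- ccdew:::new_cc_image(m, grid)
  pr <- image_profile(img, "x", coordinate = grid$ys[12])
  expect_equal(pr$value, m[, 12])
  expect_equal(pr$position, grid$xs)
  prn <- image_profile(img, "x", coordinate = grid$ys[12], normalize = TRUE)
  expect_equal(max(prn$value), 1)
  expect_equal(sum(prn$value > 0), 1) # delta stays a delta
  expect_error(image_profile(img, "x", coordinate = 50), "outside")
  # argmax tie-break: lowest linear (column-major) index
  m2 <- matrix(0, 20, 20)
  m2[5, 3] <- m2[9, 14] <- 7
  img2 <- ccdew:::new_cc_image(m2, grid)
  expect_equal(unname(image_argmax(img2)), c(grid$xs[5], grid$ys[3]))
})

test_that("Monte-Carlo sensitivity map is positive and division-safe", {
  grid <- image_grid(nx = 24, ny = 24, pixel_mm = 8, z = 90)
  sens <- estimate_sensitivity(grid, window_photopeak_171(), n_sub = 2,
                               n_photons = 3e4, seed = 2)
  expect_equal(dim(unclass(sens)), c(24L, 24L))
  expect_true(all(unclass(sens) > 0))
  expect_equal(mean(unclass(sens)), 1, tolerance = 1e-9)
  # usable as the ML-EM efficiency without error
  set.seed(10)
  ev <- make_cone_events(c(0.5, 0.5, 90), theta = runif(15, 0.4, 1.0))
  out <- mlem(ev, grid, voigt_params(0.02, 0.005), sensitivity = sens,
              iterations = 3)
  expect_true(all(is.finite(unclass(out))))
})
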