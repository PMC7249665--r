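# Monte-Carlo simulator: conservation laws, determinism, spectra, biasing.

vacuum_src <- function(n = 2e5, E0 = 171, pos = c(0, 0, 90)) {
  source_spec(E0, pos, n, emission_mode = "cone_biased", cone_fraction = 1)
}

test_that("vacuum-mode events conserve energy and respect the trigger", {
  ev <- simulate_camera(vacuum_src(), phantom_spec(attenuation = FALSE),
                        seed = 42, quiet = TRUE)
  expect_gt(nrow(ev), 100)
  resp <- detector_response()
  # summed energy cannot exceed the line energy by more than the blur allows
  sig_max <- resp$blur_scale *
    sqrt((2.3 / 2.3548)^2 * (171 / 59.5) + (3.8 / 2.3548)^2 * (171 / 81))
  expect_true(all(ev$E1 + ev$E2 <= 171 + 5 * sig_max))
  expect_true(all(ev$E1 >= 5 & ev$E2 >= 5))
  expect_true(all(ev$layer %in% 1:3))
  # hit positions inside the named volumes
  cam <- camera_geometry()$layers
  expect_true(all(abs(ev$x1) <= 16 & abs(ev$y1) <= 16))
  expect_true(all(ev$z1 <= cam$ztop[1] & ev$z1 >= cam$zbot[1]))
  for (l in 1:3) {
    sub <- ev[ev$layer == l, ]
    expect_true(all(sub$z2 <= cam$ztop[l + 1] & sub$z2 >= cam$zbot[l + 1]))
  }
})

test_that("identical seeds give identical event lists", {
  ph <- phantom_spec()
  src <- source_spec(511, c(-30, 0, 90), 5e4, emission_mode = "cone_biased",
                     cone_fraction = 0.5)
  a <- simulate_camera(src, ph, seed = 9, force_detection = TRUE, quiet = TRUE)
  b <- simulate_camera(src, ph, seed = 9, force_detection = TRUE, quiet = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # and a different seed gives a different list
  d <- simulate_camera(src, ph, seed = 10, force_detection = TRUE, quiet = TRUE)
  expect_false(identical(nrow(a) == nrow(d) && all(a$E1 == d$E1), TRUE))
})

test_that("blur-free full-absorption events are kinematically exact", {
  ev <- simulate_camera(vacuum_src(), phantom_spec(attenuation = FALSE),
                        seed = 42, blur = FALSE, quiet = TRUE)
  fa <- ev[ev$truth_full_absorption, ]
  expect_gt(nrow(fa), 50)
  expect_equal(fa$E1 + fa$E2, rep(171, nrow(fa)), tolerance = 1e-12)
  # scatterer-first events reproduce their true cone angle via the energies
  ff <- fa[fa$truth_si_first, ]
  th_E <- scatter_angle_from_energies(ff$E1, ff$E2)
  d1 <- cbind(ff$x1, ff$y1, ff$z1 - 90)
  d1 <- d1 / sqrt(rowSums(d1^2))
  d2 <- cbind(ff$x2 - ff$x1, ff$y2 - ff$y1, ff$z2 - ff$z1)
  d2 <- d2 / sqrt(rowSums(d2^2))
  th_G <- acos(pmin(1, pmax(-1, rowSums(d1 * d2))))
  expect_equal(th_E, th_G, tolerance = 1e-9)
})

test_that("energy spectrum is a weighted histogram and is linear in events", {
  ev <- make_events(E1 = c(60, 60), E2 = c(110, 111))
  sp <- energy_spectrum(ev, bin_width = 1, range = c(170, 172))
  expect_equal(sp$count, c(1, 1))
  ev$weight <- c(0.5, 0.5)
  sp <- energy_spectrum(ev, bin_width = 1, range = c(170, 172))
  expect_equal(sp$count, c(0.5, 0.5))
  expect_equal(sum(sp$count), sum(ev$weight))
  # empty input
  sp0 <- energy_spectrum(make_events(numeric(0), numeric(0)), 1, c(0, 10))
  expect_true(all(sp0$count == 0))
  # merged runs give the bin-wise sum of the individual spectra
  a <- make_events(E1 = runif(40, 30, 80), E2 = runif(40, 80, 120))
  b <- make_events(E1 = runif(25, 30, 80), E2 = runif(25, 80, 120))
  sab <- energy_spectrum(merge_listmode(a, b), 5, c(100, 220))
  expect_equal(sab$count,
               energy_spectrum(a, 5, c(100, 220))$count +
                 energy_spectrum(b, 5, c(100, 220))$count)
})

test_that("deeper sources scatter more: photopeak falls vs the continuum", {
  run <- function(z) {
    src <- source_spec(511, c(-30, 0, z), 1.5e6,
                       emission_mode = "cone_biased", cone_fraction = 0.5)
    ev <- simulate_camera(src, seed = 31, force_detection = TRUE,
                          quiet = TRUE)
    c(peak = sum(select_window(ev, window_photopeak_511())$weight),
      cont = sum(select_window(ev, energy_window(166, 186))$weight))
  }
  shallow <- run(90)   # 30 mm of water below the source
  deep <- run(170)     # 110 mm of water below the source
  # absolute photo-peak yield per primary drops with depth ...
  expect_lt(deep["peak"], shallow["peak"])
  # ... and the scattered continuum grows relative to it
  expect_gt(deep["cont"] / deep["peak"], shallow["cont"] / shallow["peak"])
})

test_that("cone-biased weighted tallies reproduce isotropic expectations", {
  ph <- phantom_spec(attenuation = FALSE)
  iso <- simulate_camera(source_spec(171, c(0, 0, 90), 5e6), ph,
                         seed = 61, quiet = TRUE)
  cone <- simulate_camera(vacuum_src(4e5), ph, seed = 62, quiet = TRUE)
  # weighted total event rate per primary (a ~3 sigma band at these budgets)
  r_iso <- sum(iso$weight) / 5e6
  r_cone <- sum(cone$weight) / 4e5
  expect_lt(abs(r_cone - r_iso) / r_iso, 0.2)
  # spectrum shape in the photo-peak region (two-sample chi-square)
  bins <- seq(150, 175, by = 5)
  h <- function(e) {
    s <- energy_spectrum(e, 5, c(150, 175))$count
    s / sum(s)
  }
  hi <- h(iso); hc <- h(cone)
  expect_lt(max(abs(hi - hc)), 0.05)
})

test_that("CdTe fluorescence escape populates exactly the vetoed class", {
  ev <- simulate_camera(vacuum_src(2e5), phantom_spec(attenuation = FALSE),
                        seed = 77, blur = FALSE, fluorescence_prob = 0.8,
                        quiet = TRUE)
  fl <- ev[ev$E1 %in% c(23.2, 27.5), ]
  expect_gt(nrow(fl), 5)
  expect_true(all(fl$layer == 1))
  expect_equal(nrow(reject_fluorescence(fl)), 0)
})
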