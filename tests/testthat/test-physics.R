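# Compton kinematics, Klein-Nishina cross-sections and attenuation tables.

test_that("scattered energy follows Compton kinematics", {
  # backscatter of an annihilation photon: E0/(1 + 2E0/mec2) = 511/3
  expect_equal(scattered_energy(511, pi), 511 / 3, tolerance = 1e-12)
  expect_equal(round(scattered_energy(511, pi)), 170)
  # forward scattering is the identity for any energy
  for (E0 in c(1, 59.5, 171, 511, 600)) {
    expect_identical(scattered_energy(E0, 0), E0)
  }
  # 90-degree scattering, hand evaluation of E0/(1 + E0/mec2)
  expect_equal(scattered_energy(171, pi / 2), 171 / (1 + 171 / 511),
               tolerance = 1e-12)
  # result always inside (E0/(1+2E0/mec2), E0]
  th <- seq(0, pi, length.out = 91)
  for (E0 in c(20, 171, 511)) {
    Ep <- scattered_energy(E0, th)
    expect_true(all(Ep <= E0 & Ep >= E0 / (1 + 2 * E0 / 511) - 1e-12))
  }
  expect_error(scattered_energy(0, 1), "positive")
  expect_error(scattered_energy(-5, 1), "positive")
  expect_error(scattered_energy(171, -0.1), "0, pi")
  expect_error(scattered_energy(171, pi + 0.1), "0, pi")
})

test_that("energy pair inverts to the scattering angle", {
  # the 511 keV backscatter split recovers theta = pi (the inverse is
  # ill-conditioned exactly at the backscatter point: dcos/dtheta = 0)
  expect_equal(scatter_angle_from_energies(511 - 511 / 3, 511 / 3), pi,
               tolerance = 1e-6)
  # algebraic round-trip on a dense (E0, theta) grid
  th <- seq(0.01, pi - 0.01, length.out = 60)
  for (E0 in c(30, 81, 171, 364, 511, 600)) {
    E2 <- scattered_energy(E0, th)
    E1 <- E0 - E2
    expect_equal(scatter_angle_from_energies(E1, E2), th, tolerance = 1e-9)
  }
  # impossible pair is flagged, not clamped
  expect_true(is.na(scatter_angle_from_energies(1, 1)))
  expect_error(scatter_angle_from_energies(0, 10), "positive")
  expect_error(scatter_angle_from_energies(10, -1), "positive")
})

test_that("Klein-Nishina density matches its closed-form integral", {
  # forward limit: ratio 1, bracket 2, prefactor 1/2
  for (E0 in c(20, 171, 511)) expect_equal(klein_nishina_pdf(E0, 0), 1)
  # solid-angle quadrature vs the closed-form total cross-section
  for (E0 in c(59.5, 171, 511)) {
    q <- integrate(function(t) klein_nishina_pdf(E0, t) * sin(t) * 2 * pi,
                   0, pi, rel.tol = 1e-10)$value
    expect_equal(q, klein_nishina_total(E0), tolerance = 1e-6)
  }
  # backscatter fraction decreases with energy (forward peaking)
  backfrac <- function(E0) {
    f <- function(t) klein_nishina_pdf(E0, t) * sin(t)
    integrate(f, pi / 2, pi)$value / integrate(f, 0, pi)$value
  }
  expect_lt(backfrac(511), backfrac(171))
})

test_that("scattering-angle sampler reproduces the analytic density", {
  set.seed(101)
  a <- sample_scatter_angle(1000, 511)
  set.seed(101)
  b <- sample_scatter_angle(1000, 511)
  expect_identical(a, b) # same seed, same stream
  expect_true(all(a >= 0 & a <= pi))

  set.seed(202)
  for (E0 in c(171, 511)) {
    th <- sample_scatter_angle(1e5, E0)
    edges <- seq(0, pi, length.out = 37)
    obs <- tabulate(findInterval(th, edges, rightmost.closed = TRUE), 36)
    p <- vapply(seq_len(36), function(i) {
      integrate(function(t) klein_nishina_pdf(E0, t) * sin(t),
                edges[i], edges[i + 1], rel.tol = 1e-9)$value
    }, numeric(1))
    p <- p / sum(p)
    gof <- suppressWarnings(chisq.test(obs, p = p))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("attenuation interpolates the embedded tables without extrapolation", {
  for (mat in c("water", "silicon", "cadmium_telluride")) {
    tab <- material_table(mat)
    expect_true(all(diff(tab$energy_kev) > 0))
    expect_lte(min(tab$energy_kev), 20)
    expect_gte(max(tab$energy_kev), 600)
    expect_true(all(tab$mu_photoelectric_mm > 0))
    expect_true(all(tab$mu_compton_mm > 0))
    # querying a tabulated energy returns the tabulated values
    att <- attenuation(mat, tab$energy_kev)
    expect_equal(att$mu_pe, tab$mu_photoelectric_mm, tolerance = 1e-12)
    expect_equal(att$mu_compton, tab$mu_compton_mm, tolerance = 1e-12)
    expect_equal(att$mu_total, att$mu_pe + att$mu_compton)
  }
  # water is Compton-dominated at the annihilation energy
  att <- attenuation("water", 511)
  expect_lt(att$mu_pe / att$mu_compton, 1e-3)
  expect_error(attenuation("water", 10), "grid")
  expect_error(attenuation("water", 1000), "grid")
  expect_error(attenuation("lead", 100))
})
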