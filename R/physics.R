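# Closed-form Compton kinematics, Klein-Nishina cross-sections and the
# embedded attenuation tables shared by the simulator and the reconstruction.

#' Energy of a Compton-scattered photon
#'
#' Compton kinematics: a photon of energy \code{E0} scattered by an angle
#' \code{theta} leaves with energy
#' \deqn{E' = E_0 / (1 + (E_0/m_e c^2)(1 - \cos\theta)).}
#' The backscatter limit (\code{theta = pi}) of a 511 keV annihilation photon
#' is 511/3 = 170.33 keV, which is why a 511 keV source contaminates energy
#' windows around 171 keV.
#'
#' @param E0 incident photon energy, keV (> 0); vectorised.
#' @param theta scattering angle, rad, in \eqn{[0, \pi]}; vectorised.
#' @return Scattered photon energy in keV.
#' @examples
#' scattered_energy(511, pi)      # 170.33 keV
#' scattered_energy(171, pi / 2)  # 171 / (1 + 171/511)
#' @export
scattered_energy <- function(E0, theta) {
  if (any(!is.finite(E0)) || any(E0 <= 0)) {
    stop("`E0` must be positive and finite")
  }
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi)) {
    stop("`theta` must lie in [0, pi]")
  }
  E0 / (1 + (E0 / 511) * (1 - cos(theta)))
}

#' Scattering angle from the two deposited energies
#'
#' Inverts the Compton kinematics for a two-hit event: with \code{E1} the
#' energy lost in the scatterer and \code{E2} the energy deposited in the
#' absorber,
#' \deqn{\cos\theta = 1 - m_e c^2 \, E_1 / (E_2 (E_1 + E_2)).}
#' After detector energy blur the right-hand side can fall outside
#' \eqn{[-1, 1]}; such kinematically impossible events are flagged by
#' returning \code{NA} so that the caller (see [drop_unphysical()]) can
#' decide to discard them.
#'
#' @param E1 scatterer energy deposit, keV (> 0); vectorised.
#' @param E2 absorber energy deposit, keV (> 0); vectorised.
#' @return Scattering angle in rad; \code{NA} where the event is unphysical.
#' @export
scatter_angle_from_energies <- function(E1, E2) {
  if (any(!is.finite(E1)) || any(E1 <= 0) || any(!is.finite(E2)) || any(E2 <= 0)) {
    stop("`E1` and `E2` must be positive and finite")
  }
  cosq <- 1 - 511 * E1 / (E2 * (E1 + E2))
  # guard the exact kinematic limits against floating-point overshoot
  tol <- 1e-9
  cosq[cosq > 1 & cosq <= 1 + tol] <- 1
  cosq[cosq < -1 & cosq >= -1 - tol] <- -1
  out <- rep(NA_real_, length(cosq))
  ok <- !is.na(cosq) & cosq >= -1 & cosq <= 1
  out[ok] <- acos(cosq[ok])
  out
}

#' Klein-Nishina differential cross-section
#'
#' Unnormalised angular density (per steradian, in units of the squared
#' classical electron radius) of Compton scattering:
#' \deqn{\frac{d\sigma}{d\Omega} = \frac{1}{2}
#'   \left(\frac{E'}{E_0}\right)^2
#'   \left(\frac{E'}{E_0} + \frac{E_0}{E'} - \sin^2\theta\right).}
#'
#' @param E0 incident photon energy, keV (> 0).
#' @param theta scattering angle, rad, in \eqn{[0, \pi]}; vectorised.
#' @return Density per steradian (dimensionless \eqn{r_e^2} units).
#' @seealso [klein_nishina_total()] for the closed-form angular integral,
#'   [sample_scatter_angle()] for sampling.
#' @export
klein_nishina_pdf <- function(E0, theta) {
  if (any(!is.finite(E0)) || any(E0 <= 0)) stop("`E0` must be positive and finite")
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi)) {
    stop("`theta` must lie in [0, pi]")
  }
  r <- scattered_energy(E0, theta) / E0
  0.5 * r^2 * (r + 1 / r - sin(theta)^2)
}

#' Closed-form total Klein-Nishina cross-section
#'
#' Integral of [klein_nishina_pdf()] over solid angle, in the same
#' \eqn{r_e^2} units; used to normalise the angular density and as the
#' analytic reference for quadrature tests.
#'
#' @param E0 incident photon energy, keV (> 0); vectorised.
#' @return Total cross-section (dimensionless \eqn{r_e^2} units).
#' @export
klein_nishina_total <- function(E0) {
  if (any(!is.finite(E0)) || any(E0 <= 0)) stop("`E0` must be positive and finite")
  a <- E0 / 511
  l <- log(1 + 2 * a)
  2 * pi * ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - l / a) +
              l / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
}

#' Sample Compton scattering angles
#'
#' Draws scattering angles with density proportional to
#' \code{klein_nishina_pdf(E0, theta) * sin(theta)} by rejection sampling
#' against the forward-scattering envelope. Randomness comes from the R
#' random number stream, so results are reproducible under [set.seed()].
#'
#' @param n number of draws.
#' @param E0 incident photon energy, keV (> 0).
#' @return Numeric vector of angles in \eqn{[0, \pi]}, rad.
#' @export
sample_scatter_angle <- function(n, E0) {
  if (length(E0) != 1 || !is.finite(E0) || E0 <= 0) {
    stop("`E0` must be a single positive energy")
  }
  cpp_sample_scatter_angle(as.integer(n), E0)
}

# ---------------------------------------------------------------------------

.load_material_tables <- function() {
  if (!is.null(.ccdew$materials)) return(.ccdew$materials)
  path <- system.file("extdata", "attenuation.tsv", package = "ccdew")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .ccdew$materials <- split(tab, tab$material)
  .ccdew$materials
}

#' Tabulated attenuation data for one material
#'
#' Returns the embedded linear attenuation table (photoelectric and Compton
#' components, mm^-1, on an ascending energy grid covering 20-600 keV) for
#' the phantom and detector materials. The Compton column is the free-electron
#' Klein-Nishina cross-section times electron density; the photoelectric
#' column is a piecewise power law anchored at standard
#' photoelectric/Compton crossover points (no K-edge structure).
#'
#' @param material one of \code{"water"}, \code{"silicon"},
#'   \code{"cadmium_telluride"}.
#' @return A data frame with columns \code{energy_kev},
#'   \code{mu_photoelectric_mm}, \code{mu_compton_mm}.
#' @export
material_table <- function(material) {
  material <- match.arg(material, c("water", "silicon", "cadmium_telluride"))
  tab <- .load_material_tables()[[material]]
  tab[order(tab$energy_kev), c("energy_kev", "mu_photoelectric_mm", "mu_compton_mm")]
}

#' Linear attenuation coefficients by log-log interpolation
#'
#' Interpolates the embedded [material_table()] in log-log space. Queries
#' outside the tabulated energy grid are refused rather than extrapolated.
#'
#' @param material one of \code{"water"}, \code{"silicon"},
#'   \code{"cadmium_telluride"}.
#' @param E photon energies, keV, inside the tabulated grid; vectorised.
#' @return A list with numeric vectors \code{mu_pe}, \code{mu_compton} and
#'   \code{mu_total} (all mm^-1).
#' @export
attenuation <- function(material, E) {
  tab <- material_table(material)
  if (any(!is.finite(E)) || any(E < min(tab$energy_kev)) || any(E > max(tab$energy_kev))) {
    stop("`E` must lie inside the tabulated grid [",
         min(tab$energy_kev), ", ", max(tab$energy_kev), "] keV")
  }
  le <- log(tab$energy_kev)
  pe <- exp(approx(le, log(tab$mu_photoelectric_mm), xout = log(E))$y)
  cc <- exp(approx(le, log(tab$mu_compton_mm), xout = log(E))$y)
  list(mu_pe = pe, mu_compton = cc, mu_total = pe + cc)
}

# attenuation table as a plain matrix for the C++ transport kernels
.att_matrix <- function(material) {
  tab <- material_table(material)
  as.matrix(tab[, c("energy_kev", "mu_photoelectric_mm", "mu_compton_mm")])
}
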