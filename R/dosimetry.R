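## Fluence / dose bookkeeping: the analytic consistency checks connecting
## delivered dose, mass stopping power and electron fluence.

#' Electron fluence implied by a dose and a mass stopping power
#'
#' Phi = dose [Gy] * 6.242e9 MeV/g/Gy / (S/rho) [MeV cm^2/g], converted to
#' um^-2. For minimally ionizing electrons (S/rho ~ 2 MeV cm^2/g) a 10 Gy
#' delivery corresponds to ~312 um^-2.
#'
#' @param dose Dose, Gy (>= 0; vectorized).
#' @param mass_stopping_power Mass stopping power, MeV cm^2/g (> 0).
#'   Default 2, the minimum-ionizing value for MeV electrons in water.
#' @return Fluence, um^-2.
#' @examples
#' fluence_from_dose(10, 2)  # ~312
#' @export
fluence_from_dose <- function(dose, mass_stopping_power = 2) {
  stopifnot(all(dose >= 0), mass_stopping_power > 0)
  # MeV per g per Gy divided by MeV*cm^2/g gives cm^-2; 1 cm^-2 = 1e-8 um^-2
  dose * .GY_MEV_PER_G / mass_stopping_power * 1e-8
}

#' Expected electron count through a sphere at a given fluence
#'
#' N = Phi * pi R^2 (the sphere's cross-sectional disk area).
#'
#' @param fluence Fluence, um^-2 (>= 0).
#' @param R Sphere radius, um (>= 0).
#' @return Expected count.
#' @examples
#' electrons_through_sphere(312, 2)  # ~3.92e3
#' @export
electrons_through_sphere <- function(fluence, R) {
  stopifnot(all(fluence >= 0), all(R >= 0))
  fluence * pi * R^2
}
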