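## Physical constants used throughout (CODATA 2018).

# Elementary charge / electron-volt [J]
.EV_J <- 1.602176634e-19

# Avogadro constant [1/mol]
.N_AVOGADRO <- 6.02214076e23

# 1 Gy expressed in MeV per gram: 1 J/kg / (1.602...e-13 J/MeV) / 1000 g/kg
.GY_MEV_PER_G <- 1 / (.EV_J * 1e6) / 1000

# mol/L produced per unit G (entities / 100 eV) per Gy, for unit density
# water (1 kg/L): dose [J/L] / (100 eV [J]) / N_A
.MOLAR_PER_G_PER_GY <- 1 / (100 * .EV_J * .N_AVOGADRO)

# Molar concentration of pure water [mol/L]
.WATER_MOLARITY <- 55.3

#' Physical constants used by the package
#'
#' Returns the conversion constants the package relies on: the electron-volt
#' in joules, the Avogadro constant, one gray expressed in MeV/g, the
#' G-value-to-concentration factor (mol/L per unit G per Gy at unit density),
#' and the molarity of water.
#'
#' @return Named list of scalars.
#' @examples
#' flash_constants()$molar_per_G_per_Gy  # ~1.0364e-7
#' @export
flash_constants <- function() {
  list(
    eV_J            = .EV_J,
    N_avogadro      = .N_AVOGADRO,
    Gy_MeV_per_g    = .GY_MEV_PER_G,
    molar_per_G_per_Gy = .MOLAR_PER_G_PER_GY,
    water_molarity  = .WATER_MOLARITY
  )
}
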