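## Physical constants and Table-of-constants values shared across the package.
## All equilibrium constants refer to ~25 C and atmospheric pressure; rate
## constants are used unmodified over the 20-30 C range of their sources.

#' @keywords internal
.micp <- list(
  R_gas   = 0.082057366,  # L atm / (mol K)
  Kw      = 1e-14,        # [H+][OH-], M^2
  K1      = 4.47e-7,      # [HCO3-][H+]/[CO2(aq)], M
  K2      = 4.68e-11,     # [CO3^2-][H+]/[HCO3-], M
  K_R3    = 1.8e-5,       # [NH4+][OH-]/[NH3(aq)], M
  K_R4    = 6.8e-4,       # [NH3(g)]/[NH3(aq)], dimensionless
  K_R5    = 1.7e-4,       # [HCO3-][H+]/[H2CO3], M
  K_R7    = 2e8,          # [CaCO3]/([Ca2+][CO3^2-]), M^-1
  K_R8    = 0.84,         # [CO2(aq)]/[CO2(g)], dimensionless
  # default buffer acid dissociation constants, HQa..HQg (M)
  buffer_Ka = c(Qa = 2.0e-10, Qb = 5.0e-9, Qc = 1.0e-6, Qd = 6.3e-5,
                Qe = 1.3e-4, Qf = 4.0e-3, Qg = 7.9e-8),
  mm_urea  = 60.06,       # g/mol
  mm_cacl2 = 110.98       # g/mol
)

#' Molarity of an ideal-gas component in the headspace
#'
#' Converts a volume fraction of a gas at a given total pressure and
#' temperature into a molar concentration via the ideal gas law,
#' \eqn{c = f P / (R T)}.
#'
#' @param volume_fraction volume (= mole) fraction of the component, in
#'   \[0, 1\].
#' @param pressure total pressure in atm.
#' @param temperature temperature in K.
#' @return concentration in mol/L of gas phase.
#' @examples
#' gas_molarity(1.0)          # pure CO2 at 1 atm, 30 C: ~0.0402 M
#' gas_molarity(0.82)         # ~0.033 M
#' @export
gas_molarity <- function(volume_fraction, pressure = 1, temperature = 303.15) {
  stopifnot(volume_fraction >= 0, volume_fraction <= 1,
            pressure > 0, temperature > 0)
  volume_fraction * pressure / (.micp$R_gas * temperature)
}

#' Convert a mass concentration to molarity
#'
#' @param g_per_l mass concentration in g/L.
#' @param molar_mass molar mass in g/mol (e.g. urea 60.06, CaCl2 110.98).
#' @return molar concentration in mol/L.
#' @examples
#' mass_to_molar(20, 60.06)   # 20 g/L urea ~ 0.333 M
#' @export
mass_to_molar <- function(g_per_l, molar_mass) {
  stopifnot(g_per_l >= 0, molar_mass > 0)
  g_per_l / molar_mass
}
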