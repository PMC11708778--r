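# Physical constants, fixed to 7 significant figures for reproducibility.
# Units used throughout the package: lengths in angstrom, energies in
# kcal/mol, charges in elementary-charge units (a.u.), wavenumbers in cm^-1,
# temperatures in K.

#' Physical constants used by enzmech
#'
#' A named list of the fixed physical constants the package computes with:
#' \describe{
#'   \item{c2}{Second radiation constant \eqn{hc/k_B}, 1.4387769 cm K.
#'     Converts a wavenumber to a vibrational temperature.}
#'   \item{R_kcal}{Molar gas constant, 1.987204e-3 kcal/(mol K).}
#'   \item{coulomb}{Coulomb energy prefactor for point charges in elementary
#'     charge units at angstrom separation, 332.0637 kcal A/(mol e^2).}
#'   \item{h, kB, avogadro, amu, cal}{SI values (J s, J/K, 1/mol, kg, J/cal) used
#'     only for the optional ideal-gas translational/rotational terms.}
#' }
#'
#' @return A named list of numeric constants.
#' @examples
#' enzmech_constants()$c2
#' @export
enzmech_constants <- function() {
  list(
    c2      = 1.4387769,      # cm K
    R_kcal  = 1.987204e-3,    # kcal / (mol K)
    coulomb = 332.0637,       # kcal A / (mol e^2)
    h       = 6.626070e-34,   # J s
    kB      = 1.380649e-23,   # J / K
    avogadro = 6.022141e23,   # 1 / mol
    amu     = 1.660539e-27,   # kg
    cal     = 4.184           # J
  )
}

.const <- enzmech_constants()

# Standard atomic masses (amu) for the elements that occur in QM-region
# models of organic active sites; used only by the trans/rot terms.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, Na = 22.990, K = 39.098,
  Mg = 24.305, Ca = 40.078, Zn = 65.38, Fe = 55.845, X = 0
)
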