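#' Physical constants (SI, CODATA 2018 exact/recommended values)
#'
#' All quantities the model needs, in strict SI. Energies elsewhere in the
#' package are reported in eV and capacitances additionally in uF/cm^2, but
#' every formula evaluates in these units.
#'
#' @return A named list of class `physical_constants` with elements
#'   `e` (elementary charge, C), `hbar` (reduced Planck constant, J s),
#'   `kB` (Boltzmann constant, J/K), `eps0` (vacuum permittivity, F/m),
#'   `N_A` (Avogadro constant, 1/mol), `F_const` (Faraday constant, C/mol),
#'   `R_gas` (molar gas constant, J/mol/K), `c0` (speed of light, m/s) and
#'   `Z0` (free-space impedance, exactly 120*pi Ohm in the Gaussian-rounded
#'   convention used throughout the transmission-line model).
#' @examples
#' k <- physical_constants()
#' k$Z0 / pi   # 120
#' @export
physical_constants <- function() {
  structure(list(
    e       = 1.602176634e-19,
    hbar    = 1.054571817e-34,
    kB      = 1.380649e-23,
    eps0    = 8.8541878128e-12,
    N_A     = 6.02214076e23,
    F_const = 96485.33212,
    R_gas   = 8.314462618,
    c0      = 299792458,
    Z0      = 120 * pi
  ), class = "physical_constants")
}

# Internal singleton to avoid rebuilding the list in hot loops.
.const <- list(
  e = 1.602176634e-19, hbar = 1.054571817e-34, kB = 1.380649e-23,
  eps0 = 8.8541878128e-12, N_A = 6.02214076e23, F_const = 96485.33212,
  R_gas = 8.314462618, c0 = 299792458, Z0 = 120 * pi
)

#' Convert a mass concentration in g/L to mol/m^3
#'
#' @param c_gL concentration in g/L.
#' @param molar_mass molar mass in g/mol.
#' @return concentration in mol/m^3 (`c_gL / molar_mass * 1000`).
#' @examples
#' g_per_L_to_mol_m3(1.18, 11800)  # 0.1 mol/m^3
#' @export
g_per_L_to_mol_m3 <- function(c_gL, molar_mass) {
  stopifnot(molar_mass > 0, c_gL >= 0)
  c_gL / molar_mass * 1000
}

#' @rdname g_per_L_to_mol_m3
#' @param c_molm3 concentration in mol/m^3.
#' @export
mol_m3_to_g_per_L <- function(c_molm3, molar_mass) {
  stopifnot(molar_mass > 0)
  c_molm3 * molar_mass / 1000
}

#' Convert sheet carrier density between cm^-2 and m^-2
#' @param n_cm2,n_m2 sheet density in the unit the name states.
#' @return density in the other unit.
#' @export
cm2_to_m2 <- function(n_cm2) n_cm2 * 1e4

#' @rdname cm2_to_m2
#' @export
m2_to_cm2 <- function(n_m2) n_m2 * 1e-4

#' Convert a capacitance per area from F/m^2 to uF/cm^2
#' @param C_Fm2 capacitance per unit area in F/m^2.
#' @export
Fm2_to_uFcm2 <- function(C_Fm2) C_Fm2 * 1e2
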