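# Declarative input specifications: the electrolyte, the analyte protein,
# the adsorption isotherm linking bulk concentration to interface charge,
# and graphene's optical parameters. Constructors validate and fill defaults;
# all fields are strict SI.

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}
.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name), call. = FALSE)
  invisible(x)
}

#' Electrolyte specification
#'
#' Composition and dielectric description of the aqueous electrolyte at the
#' graphene interface. Unstated compact-layer parameters default to
#' conventional aqueous values (eps_H = 6, d_H = 0.5 nm, eps_r = 78.5,
#' T = 300 K), all configurable.
#'
#' @param c_salt bulk monovalent salt concentration (mol/m^3; 1 mol/m^3 = 1 mM).
#' @param z_salt ion valence (default 1).
#' @param eps_r relative permittivity of the diffuse layer.
#' @param eps_H relative permittivity inside the Helmholtz layer.
#' @param d_H Helmholtz layer thickness / solvated ion size (m).
#' @param T temperature (K).
#' @param eps_H2O static relative permittivity of pure water.
#' @param A_DF Debye-Falkenhagen coefficient (permittivity per sqrt(mol/m^3)),
#'   for the concentration correction eps_sol = eps_H2O + A_DF*sqrt(c).
#' @return object of class `electrolyte_spec`.
#' @examples
#' es <- electrolyte_spec(c_salt = 1)
#' debye_length(es$c_salt, es$eps_r, es$T)  # ~9.7 nm at 300 K
#' @export
electrolyte_spec <- function(c_salt = 1, z_salt = 1, eps_r = 78.5,
                             eps_H = 6, d_H = 0.5e-9, T = 300,
                             eps_H2O = 78.5, A_DF = 0.12) {
  .check_pos(c_salt, "c_salt"); .check_pos(z_salt, "z_salt")
  .check_pos(eps_r, "eps_r");   .check_pos(eps_H, "eps_H")
  .check_pos(d_H, "d_H");       .check_pos(T, "T")
  .check_pos(eps_H2O, "eps_H2O"); .check_nonneg(A_DF, "A_DF")
  if (!(eps_H <= eps_r && eps_r <= eps_H2O))
    warning("expected eps_H <= eps_r <= eps_H2O; check permittivity inputs",
            call. = FALSE)
  structure(list(c_salt = c_salt, z_salt = z_salt, eps_r = eps_r,
                 eps_H = eps_H, d_H = d_H, T = T,
                 eps_H2O = eps_H2O, A_DF = A_DF),
            class = "electrolyte_spec")
}

#' Analyte protein specification
#'
#' Defaults describe beta-2-microglobulin: net charge -2 at neutral pH,
#' effective diameter 4 nm, self-diffusion coefficient 0.0135 A^2/ps
#' (= 1.35e-10 m^2/s) at 300 K, molar mass ~11.8 kDa. These numbers enter
#' the model as fixed input constants.
#'
#' @param z_p net valence (dimensionless).
#' @param diameter effective protein diameter (m).
#' @param D_p self-diffusion coefficient (m^2/s).
#' @param molar_mass molar mass (g/mol).
#' @param c_bulk bulk mass concentration (g/L).
#' @return object of class `protein_spec`.
#' @export
protein_spec <- function(z_p = -2, diameter = 4e-9, D_p = 1.35e-10,
                         molar_mass = 11800, c_bulk = 0) {
  .check_pos(diameter, "diameter"); .check_pos(D_p, "D_p")
  .check_pos(molar_mass, "molar_mass"); .check_nonneg(c_bulk, "c_bulk")
  if (!is.numeric(z_p) || length(z_p) != 1L || !is.finite(z_p))
    stop("'z_p' must be a single finite number", call. = FALSE)
  structure(list(z_p = z_p, diameter = diameter, D_p = D_p,
                 molar_mass = molar_mass, c_bulk = c_bulk),
            class = "protein_spec")
}

#' Adsorption model linking bulk concentration to induced carrier density
#'
#' The sensing interface converts the bulk analyte concentration into an
#' effective adsorbed surface charge and hence an induced graphene carrier
#' density. Two functional forms are supported: `linear`
#' (n = n0 + |z_p| Gamma_max K_ads c) and `langmuir`
#' (n = n0 + |z_p| Gamma_max K_ads c / (1 + K_ads c)); the Langmuir form is
#' the default because it covers both the linear low-concentration regime
#' and saturation at high concentration.
#'
#' @param kind `"linear"` or `"langmuir"`.
#' @param K_ads affinity constant (L/g).
#' @param Gamma_max saturation surface site density (m^-2).
#' @param n0 baseline carrier density at zero analyte (m^-2). The default
#'   `NULL` resolves to the density whose Fermi energy is 0.3 eV (the
#'   absorber's optimal baseline doping) at `v_f` = 1e6 m/s.
#' @param v_f Fermi velocity used to resolve a `NULL` `n0` (m/s).
#' @return object of class `adsorption_model`.
#' @export
adsorption_model <- function(kind = c("langmuir", "linear"), K_ads = 10,
                             Gamma_max = 1e16, n0 = NULL, v_f = 1e6) {
  kind <- match.arg(kind)
  .check_pos(K_ads, "K_ads"); .check_pos(Gamma_max, "Gamma_max")
  if (is.null(n0)) n0 <- density_for_fermi_energy(0.3, v_f)
  .check_nonneg(n0, "n0")
  structure(list(kind = kind, K_ads = K_ads, Gamma_max = Gamma_max, n0 = n0),
            class = "adsorption_model")
}

#' Graphene optical parameters
#'
#' @param E_f Fermi energy (eV).
#' @param tau carrier relaxation time (s); default 1e-13 s, typical of CVD
#'   graphene (the source model does not state a value).
#' @param T temperature (K).
#' @param v_f Fermi velocity (m/s).
#' @return object of class `graphene_optical_params`.
#' @export
graphene_optical_params <- function(E_f = 0.3, tau = 1e-13, T = 300,
                                    v_f = 1e6) {
  .check_nonneg(E_f, "E_f"); .check_pos(tau, "tau")
  .check_pos(T, "T"); .check_pos(v_f, "v_f")
  structure(list(E_f = E_f, tau = tau, T = T, v_f = v_f),
            class = "graphene_optical_params")
}

#' @export
print.electrolyte_spec <- function(x, ...) {
  cat("Electrolyte: c_salt =", x$c_salt, "mol/m^3, eps_r =", x$eps_r,
      ", eps_H =", x$eps_H, ", d_H =", x$d_H * 1e9, "nm, T =", x$T, "K\n")
  invisible(x)
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf(
    "Protein: z = %+g, diameter = %g nm, D = %.3g m^2/s, M = %g g/mol, c_bulk = %g g/L\n",
    x$z_p, x$diameter * 1e9, x$D_p, x$molar_mass, x$c_bulk))
  invisible(x)
}
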