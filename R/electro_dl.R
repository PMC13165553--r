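# Closed-form electric-double-layer and graphene quantum-capacitance
# electrostatics, plus the self-consistent gating relation between
# interface charge and the graphene Fermi level. All inputs/outputs SI;
# energies in eV where stated.

#' Helmholtz (compact-layer) capacitance per unit area
#'
#' `C_H = eps0 * eps_H / d_H`: a parallel-plate capacitor formed by the
#' monolayer of solvated counter-ions at distance `d_H` from the electrode.
#'
#' @param eps_H relative permittivity inside the Helmholtz layer.
#' @param d_H Helmholtz layer thickness (m).
#' @return capacitance per area (F/m^2).
#' @examples
#' helmholtz_capacitance(6, 0.5e-9)  # ~0.106 F/m^2
#' @export
helmholtz_capacitance <- function(eps_H, d_H) {
  .check_pos(eps_H, "eps_H"); .check_pos(d_H, "d_H")
  .const$eps0 * eps_H / d_H
}

#' Debye screening length of a monovalent electrolyte
#'
#' `lambda_D = sqrt(eps_r * eps0 * kB * T / (2 * c_num * e^2))` with
#' `c_num` the bulk number density (the molar concentration times the
#' Avogadro constant).
#'
#' @param c_salt bulk salt concentration (mol/m^3).
#' @param eps_r relative permittivity of the diffuse layer.
#' @param T temperature (K).
#' @return Debye length (m).
#' @examples
#' debye_length(1, 78.5, 298)  # ~9.6 nm for 1 mM
#' @export
debye_length <- function(c_salt, eps_r, T) {
  .check_pos(c_salt, "c_salt"); .check_pos(eps_r, "eps_r"); .check_pos(T, "T")
  c_num <- c_salt * .const$N_A
  sqrt(eps_r * .const$eps0 * .const$kB * T / (2 * c_num * .const$e^2))
}

#' Gouy-Chapman (diffuse-layer) differential capacitance per unit area
#'
#' `C_GC = (eps_r * eps0 / lambda_D) * cosh(z e phi / (2 kB T))`. The cosh
#' is evaluated in log space so large potentials saturate at the double
#' precision ceiling instead of overflowing.
#'
#' @param c_salt bulk salt concentration (mol/m^3).
#' @param phi potential drop across the diffuse layer (V).
#' @param eps_r relative permittivity of the diffuse layer.
#' @param T temperature (K).
#' @param z ion valence (default 1).
#' @return capacitance per area (F/m^2), vectorized over `phi`.
#' @export
gouy_chapman_capacitance <- function(c_salt, phi, eps_r, T, z = 1) {
  lam <- debye_length(c_salt, eps_r, T)
  x <- abs(z * .const$e * phi / (2 * .const$kB * T))
  # cosh(x) = exp(x)(1 + exp(-2x))/2; cap the exponent at log(.Machine$double.xmax)
  ch <- ifelse(x < 700, cosh(x), exp(pmin(x, 709)) / 2)
  eps_r * .const$eps0 / lam * ch
}

#' Series combination of two capacitances (Stern model / total capacitance)
#'
#' The Stern picture treats the compact (Helmholtz) and diffuse
#' (Gouy-Chapman) layers as capacitors in series; the same reciprocal sum
#' combines the double-layer capacitance with graphene's quantum
#' capacitance.
#'
#' @param C1,C2 capacitances per area (F/m^2), both positive.
#' @return `(1/C1 + 1/C2)^-1` (F/m^2).
#' @export
stern_series <- function(C1, C2) {
  if (any(C1 <= 0) || any(C2 <= 0))
    stop("series capacitances must be positive", call. = FALSE)
  1 / (1 / C1 + 1 / C2)
}

#' @rdname stern_series
#' @export
total_capacitance <- function(C1, C2) stern_series(C1, C2)

#' Graphene quantum capacitance, full finite-temperature form
#'
#' `C_Q = (2 e^2 kB T / (pi (hbar v_f)^2)) * ln[2(1 + cosh(e V_ch / kB T))]`,
#' derived from the linear density of states of ideal graphene. At the
#' Dirac point (`V_ch = 0`) this leaves the finite thermal minimum
#' `... * ln 4` (~0.84 uF/cm^2 at 300 K).
#'
#' @param V_ch graphene channel potential `E_f / e` (V).
#' @param T temperature (K).
#' @param v_f Fermi velocity (m/s).
#' @return capacitance per area (F/m^2), vectorized over `V_ch`.
#' @export
quantum_capacitance_full <- function(V_ch, T = 300, v_f = 1e6) {
  .check_pos(T, "T"); .check_pos(v_f, "v_f")
  x <- abs(.const$e * V_ch / (.const$kB * T))
  # 2(1 + cosh x) = e^x (1 + e^-x)^2, so ln(2(1+cosh x)) = x + 2 log1p(e^-x)
  lnterm <- x + 2 * log1p(exp(-x))
  pref <- 2 * .const$e^2 * .const$kB * T / (pi * (.const$hbar * v_f)^2)
  pref * lnterm
}

#' Graphene quantum capacitance, degenerate (T -> 0) limit
#'
#' `C_Q = 2 e^2 sqrt(n / pi) / (hbar v_f)`, the reduction of the full
#' finite-temperature expression when `e V_ch >> kB T`.
#'
#' @param n sheet carrier density (m^-2).
#' @param v_f Fermi velocity (m/s).
#' @return capacitance per area (F/m^2), vectorized over `n`.
#' @export
quantum_capacitance_degenerate <- function(n, v_f = 1e6) {
  if (any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  .check_pos(v_f, "v_f")
  2 * .const$e^2 * sqrt(n / pi) / (.const$hbar * v_f)
}

#' Graphene Fermi energy from sheet carrier density
#'
#' `E_f(n) = hbar v_f sqrt(pi n) / e` in eV. With `n` in cm^-2 and
#' `v_f` = 1e6 m/s the prefactor is 1.16e-7 eV.
#'
#' @param n sheet carrier density (m^-2).
#' @param v_f Fermi velocity (m/s).
#' @return Fermi energy (eV), vectorized over `n`.
#' @examples
#' fermi_energy_from_density(1e16)  # ~0.117 eV at 1e12 cm^-2
#' @export
fermi_energy_from_density <- function(n, v_f = 1e6) {
  if (any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  .check_pos(v_f, "v_f")
  .const$hbar * v_f * sqrt(pi * n) / .const$e
}

#' Carrier density at a given Fermi energy (inverse of E_f(n))
#' @param E_f Fermi energy (eV).
#' @param v_f Fermi velocity (m/s).
#' @return sheet density (m^-2).
#' @export
density_for_fermi_energy <- function(E_f, v_f = 1e6) {
  if (any(E_f < 0)) stop("'E_f' must be non-negative", call. = FALSE)
  (E_f * .const$e / (.const$hbar * v_f))^2 / pi
}

#' Total gating energy of electrolyte-gated graphene
#'
#' `E_g = E_f(n) + n e / C` (eV): the band-filling term plus the
#' electrostatic potential drop across the interfacial capacitance `C`
#' (`C_EDL` in the Stern picture, the series `C_total` once quantum
#' capacitance is included).
#'
#' @param n sheet carrier density (m^-2).
#' @param C interfacial capacitance per area (F/m^2).
#' @param v_f Fermi velocity (m/s).
#' @return gating energy (eV), vectorized over `n`.
#' @export
gating_energy <- function(n, C, v_f = 1e6) {
  if (any(C <= 0)) stop("'C' must be positive", call. = FALSE)
  fermi_energy_from_density(n, v_f) + n * .const$e / C
}

#' Invert the gating relation: carrier density for a target gating energy
#'
#' Finds the unique root of `gating_energy(n, C) = E_g` on
#' n in [0, 1e20 m^-2] by Brent bracketing; the residual is polished below
#' 1e-9 eV. The gating energy is strictly increasing in `n`, so the root is
#' unique.
#'
#' @param E_g target gating energy (eV), >= 0.
#' @param C interfacial capacitance per area (F/m^2).
#' @param v_f Fermi velocity (m/s).
#' @return sheet carrier density (m^-2).
#' @export
solve_density_for_gating <- function(E_g, C, v_f = 1e6) {
  if (E_g < 0) stop("'E_g' must be non-negative", call. = FALSE)
  if (E_g == 0) return(0)
  f <- function(n) gating_energy(n, C, v_f) - E_g
  hi <- 1e20
  if (f(hi) < 0) stop("no bracket for gating inversion: E_g too large", call. = FALSE)
  r <- stats::uniroot(f, c(0, hi), tol = 1e-14 * hi, maxiter = 200)
  n <- r$root
  # Newton polish to push the energy residual below 1e-9 eV
  for (i in 1:50) {
    res <- f(n)
    if (abs(res) <= 1e-12) break
    dEdn <- .const$hbar * v_f * sqrt(pi) / (2 * sqrt(max(n, 1e-30)) * .const$e) +
      .const$e / C
    n <- max(n - res / dEdn, 0)
  }
  if (abs(f(n)) > 1e-9)
    stop("gating inversion did not reach 1e-9 eV residual", call. = FALSE)
  n
}

#' Carrier density induced by a bulk analyte concentration
#'
#' Adsorption at the sensing interface converts the bulk concentration into
#' an adsorbed surface density `Gamma(c)` and hence (each molecule carrying
#' `z_p` elementary charges) an induced carrier density on top of the
#' baseline `n0`:
#' linear: `n = n0 + |z_p| Gamma_max K_ads c`;
#' Langmuir: `n = n0 + |z_p| Gamma_max K_ads c / (1 + K_ads c)`.
#' Monotone non-decreasing in `c`.
#'
#' @param protein a [protein_spec()]; `c_bulk` (g/L) and `z_p` are used.
#' @param model an [adsorption_model()].
#' @return sheet carrier density (m^-2).
#' @export
carrier_density_from_concentration <- function(protein, model) {
  stopifnot(inherits(protein, "protein_spec"), inherits(model, "adsorption_model"))
  cb <- protein$c_bulk
  occ <- switch(model$kind,
    linear   = model$K_ads * cb,
    langmuir = model$K_ads * cb / (1 + model$K_ads * cb))
  model$n0 + abs(protein$z_p) * model$Gamma_max * occ
}

#' Linear-screening potential profile in the diffuse layer
#'
#' `phi(x) = phi0 * exp(-x / lambda_D)` on the planar domain, the
#' Debye-Hueckel solution the full nonlinear solver reduces to at small
#' surface potential.
#'
#' @param phi0 surface potential at x = 0 (V).
#' @param lambda_D Debye length (m).
#' @param x_grid distances from the interface (m), >= 0.
#' @return potentials (V) on `x_grid`.
#' @export
potential_profile <- function(phi0, lambda_D, x_grid) {
  .check_pos(lambda_D, "lambda_D")
  if (any(x_grid < 0)) stop("'x_grid' must be non-negative", call. = FALSE)
  phi0 * exp(-x_grid / lambda_D)
}

#' Assemble the full capacitance ladder for an interface state
#'
#' Evaluates the Helmholtz, Gouy-Chapman, Stern-series, quantum, and total
#' series capacitances (plus the Debye length) for a given electrolyte and
#' graphene state.
#'
#' @param electrolyte an [electrolyte_spec()].
#' @param phi diffuse-layer potential drop used in the Gouy-Chapman term (V).
#' @param n graphene sheet carrier density (m^-2), sets the quantum
#'   capacitance through the channel potential `E_f(n)/e`.
#' @param v_f Fermi velocity (m/s).
#' @return object of class `capacitance_set` with fields `C_H`, `C_GC`,
#'   `C_EDL`, `C_Q`, `C_total` (F/m^2) and `lambda_D` (m).
#' @export
capacitance_set <- function(electrolyte, phi = 0, n, v_f = 1e6) {
  stopifnot(inherits(electrolyte, "electrolyte_spec"))
  C_H  <- helmholtz_capacitance(electrolyte$eps_H, electrolyte$d_H)
  C_GC <- gouy_chapman_capacitance(electrolyte$c_salt, phi, electrolyte$eps_r,
                                   electrolyte$T, electrolyte$z_salt)
  C_EDL <- stern_series(C_H, C_GC)
  V_ch <- fermi_energy_from_density(n, v_f)  # volts numerically equal to eV
  C_Q <- quantum_capacitance_full(V_ch, electrolyte$T, v_f)
  structure(list(
    C_H = C_H, C_GC = C_GC, C_EDL = C_EDL, C_Q = C_Q,
    C_total = total_capacitance(C_EDL, C_Q),
    lambda_D = debye_length(electrolyte$c_salt, electrolyte$eps_r, electrolyte$T)
  ), class = "capacitance_set")
}

#' Gating state of the graphene channel
#'
#' @param n sheet carrier density (m^-2).
#' @param C interfacial capacitance per area (F/m^2).
#' @param v_f Fermi velocity (m/s).
#' @return object of class `gating_state` with `n` (m^-2), `E_f` (eV),
#'   `V_ch` (V), `phi` (V, the interfacial drop `n e / C`), `E_g` (eV) and
#'   `v_f` (m/s).
#' @export
gating_state <- function(n, C, v_f = 1e6) {
  E_f <- fermi_energy_from_density(n, v_f)
  phi <- n * .const$e / C
  structure(list(n = n, E_f = E_f, V_ch = E_f, phi = phi,
                 E_g = E_f + phi, v_f = v_f),
            class = "gating_state")
}

#' @export
print.capacitance_set <- function(x, ...) {
  cat(sprintf("Capacitances (uF/cm^2): C_H=%.4g C_GC=%.4g C_EDL=%.4g C_Q=%.4g C_total=%.4g\n",
              Fm2_to_uFcm2(x$C_H), Fm2_to_uFcm2(x$C_GC), Fm2_to_uFcm2(x$C_EDL),
              Fm2_to_uFcm2(x$C_Q), Fm2_to_uFcm2(x$C_total)))
  cat(sprintf("Debye length: %.4g nm\n", x$lambda_D * 1e9))
  invisible(x)
}

#' @export
print.gating_state <- function(x, ...) {
  cat(sprintf("Gating state: n = %.4g cm^-2, E_f = %.4g eV, phi = %.4g V, E_g = %.4g eV\n",
              m2_to_cm2(x$n), x$E_f, x$phi, x$E_g))
  invisible(x)
}
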