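# Frequency-dependent graphene sheet conductivity (Kubo/RPA intraband +
# interband) and exact 1-D transfer-matrix optics of a PEC-backed absorber
# stack at normal incidence. Time convention exp(-i omega t): lossy media
# have Im(n) > 0 and passive sheets Re(sigma) > 0; with that convention the
# inductive Drude sheet pushes the absorber resonance above the quarter-wave
# frequency and the resonance blueshifts with increasing Fermi level.

#' Intraband (Drude-like) graphene sheet conductivity
#'
#' RPA result
#' `sigma_intra = (2i kB T e^2 / (pi hbar^2 (omega + i/tau))) * ln(2 cosh(E_f / 2 kB T))`.
#' For `E_f >> kB T` this reduces to the Drude form
#' `i e^2 E_f / (pi hbar^2 (omega + i/tau))`.
#'
#' @param params a [graphene_optical_params()].
#' @param omega angular frequencies (rad/s), > 0.
#' @return complex sheet conductivity (S) on `omega`.
#' @export
sigma_intra <- function(params, omega) {
  stopifnot(inherits(params, "graphene_optical_params"), all(omega > 0))
  kBT <- .const$kB * params$T
  EfJ <- params$E_f * .const$e
  x <- EfJ / (2 * kBT)
  lnch <- x + log1p(exp(-2 * x))            # ln(2 cosh x), overflow-safe
  pref <- 2i * kBT * .const$e^2 / (pi * .const$hbar^2)
  pref * lnch / (omega + 1i / params$tau)
}

#' Interband graphene sheet conductivity
#'
#' Standard Kubo form (default):
#' `sigma_inter = (e^2 / 4 hbar) * [ 1/2 + (1/pi) atan((hbar w - 2 E_f)/(2 kB T))
#'   - (i / 2 pi) ln( (hbar w + 2 E_f)^2 / ((hbar w - 2 E_f)^2 + (2 kB T)^2) ) ]`.
#' The Pauli-blocking edge sits at `hbar w = 2 E_f` and the high-frequency
#' limit of the real part is the universal conductivity `e^2 / 4 hbar`.
#' `form = "printed"` evaluates the variant with `E_f` in place of `2 E_f`
#' and an additive `1/pi`, kept for comparison with a commonly typeset
#' rendition of the same expression.
#'
#' @param params a [graphene_optical_params()].
#' @param omega angular frequencies (rad/s), > 0.
#' @param form `"standard"` (default) or `"printed"`.
#' @return complex sheet conductivity (S) on `omega`.
#' @export
sigma_inter <- function(params, omega, form = c("standard", "printed")) {
  stopifnot(inherits(params, "graphene_optical_params"), all(omega > 0))
  form <- match.arg(form)
  kBT <- .const$kB * params$T
  EfJ <- params$E_f * .const$e
  hw <- .const$hbar * omega
  sig0 <- .const$e^2 / (4 * .const$hbar)
  if (form == "standard") {
    re <- 0.5 + atan((hw - 2 * EfJ) / (2 * kBT)) / pi
    im <- -log((hw + 2 * EfJ)^2 / ((hw - 2 * EfJ)^2 + (2 * kBT)^2)) / (2 * pi)
  } else {
    re <- 0.5 + 1 / pi + atan((hw - EfJ) / (2 * kBT))
    im <- -log((hw + EfJ)^2 / ((hw - EfJ)^2 + (2 * kBT)^2)) / (2 * pi)
  }
  sig0 * complex(real = re, imaginary = im)
}

#' Total graphene sheet conductivity
#'
#' `sigma = sigma_intra + sigma_inter` (S per square).
#'
#' @inheritParams sigma_inter
#' @return list with complex vectors `sigma_intra`, `sigma_inter`,
#'   `sigma_total` and the inputs, class `surface_conductivity`.
#' @export
graphene_conductivity <- function(params, omega, form = c("standard", "printed")) {
  form <- match.arg(form)
  si <- sigma_intra(params, omega)
  se <- sigma_inter(params, omega, form)
  structure(list(omega_grid = omega, sigma_intra = si, sigma_inter = se,
                 sigma_total = si + se, params = params, form = form),
            class = "surface_conductivity")
}

#' Amplitude coefficients at a conductive interface
#'
#' Normal-incidence reflection and transmission of a wave incident from
#' refractive index `n1` onto `n2` through a zero-thickness sheet of
#' conductivity `sigma_s`:
#' `r = (n1 - n2 - sigma_s Z0) / (n1 + n2 + sigma_s Z0)`,
#' `t = 2 n1 / (n1 + n2 + sigma_s Z0)`.
#' Tangential-field continuity makes `1 + r = t` an exact algebraic
#' identity of these coefficients; with `sigma_s = 0` they reduce to the
#' Fresnel normal-incidence formulas.
#'
#' @param n1,n2 (complex) refractive indices, `Re > 0`.
#' @param sigma_s complex sheet conductivity (S), scalar or vector.
#' @return list of complex vectors `r` and `t`.
#' @export
interface_coefficients <- function(n1, n2, sigma_s = 0) {
  if (any(Re(n1) <= 0) || any(Re(n2) <= 0))
    stop("refractive indices must have positive real part", call. = FALSE)
  n1 <- as.complex(n1); n2 <- as.complex(n2); sigma_s <- as.complex(sigma_s)
  den <- n1 + n2 + sigma_s * .const$Z0
  list(r = (n1 - n2 - sigma_s * .const$Z0) / den, t = 2 * n1 / den)
}

#' Dielectric slab layer for a stack
#' @param thickness slab thickness (m), > 0.
#' @param eps complex relative permittivity (or give `n`).
#' @param n complex refractive index (alternative to `eps`).
#' @return layer element for [layer_stack()].
#' @export
slab_layer <- function(thickness, eps = NULL, n = NULL) {
  stopifnot(thickness > 0)
  if (is.null(n)) {
    stopifnot(!is.null(eps))
    n <- sqrt(as.complex(eps))
  }
  if (Im(n) < 0) n <- Conj(n)  # lossy convention Im(n) >= 0
  list(type = "slab", thickness = thickness, n = n)
}

#' Conductive-sheet layer (e.g. a graphene monolayer) for a stack
#' @param sigma sheet conductivity: a complex scalar/vector over the
#'   frequency grid, or a [graphene_optical_params()] evaluated per grid.
#' @param form interband form passed to [graphene_conductivity()] when
#'   `sigma` is a parameter set.
#' @return layer element for [layer_stack()].
#' @export
sheet_layer <- function(sigma, form = "standard") {
  list(type = "sheet", sigma = sigma, form = form)
}

#' Layer stack for the 1-D absorber model
#'
#' Ordered from the (semi-infinite) incidence superstrate down to the
#' backing. Slabs have finite thickness; sheets are zero-thickness
#' conductive interfaces between neighbouring media.
#'
#' @param n_in refractive index of the incidence superstrate.
#' @param layers list of [slab_layer()] / [sheet_layer()] elements, in
#'   propagation order.
#' @param backing `"PEC"` (perfect electric conductor, transmission
#'   identically zero) or a complex refractive index of a semi-infinite
#'   substrate.
#' @return object of class `layer_stack`.
#' @export
layer_stack <- function(n_in = 1, layers = list(), backing = "PEC") {
  stopifnot(Re(n_in) > 0)
  is_pec <- identical(backing, "PEC")
  if (!is_pec) stopifnot(is.numeric(backing) || is.complex(backing))
  has_sheet <- any(vapply(layers, function(l) l$type == "sheet", logical(1)))
  structure(list(n_in = n_in, layers = layers, backing = backing,
                 pec = is_pec, has_sheet = has_sheet),
            class = "layer_stack")
}

# Resolve a sheet's conductivity on the angular-frequency grid.
.sheet_sigma <- function(layer, omega) {
  s <- layer$sigma
  if (inherits(s, "graphene_optical_params"))
    return(graphene_conductivity(s, omega, layer$form)$sigma_total)
  rep_len(as.complex(s), length(omega))
}

#' Spectral response of a layer stack (transfer-matrix method)
#'
#' Cascades the 2x2 characteristic matrices of the slabs and the
#' jump-condition matrices of the conductive sheets at normal incidence and
#' returns reflectance, transmittance and absorption. With a PEC backing
#' the transmittance is identically zero and `A = 1 - R` holds to machine
#' precision by construction of the energy bookkeeping.
#'
#' @param stack a [layer_stack()].
#' @param f_grid frequencies (THz).
#' @param sigma_per_interface optional list overriding each sheet's
#'   conductivity (complex scalar/vector per sheet, in stack order).
#' @return object of class `spectral_response`: list with `f_grid` (THz),
#'   `R`, `T_trans`, `A`, and complex amplitudes `r`, `t`.
#' @export
stack_response <- function(stack, f_grid, sigma_per_interface = NULL) {
  stopifnot(inherits(stack, "layer_stack"), all(f_grid > 0))
  omega <- 2 * pi * f_grid * 1e12
  nf <- length(omega)
  one <- rep(1 + 0i, nf); zero <- rep(0 + 0i, nf)
  m11 <- one; m12 <- zero; m21 <- zero; m22 <- one
  Z0 <- .const$Z0
  k0 <- omega / .const$c0
  sheet_idx <- 0
  for (layer in stack$layers) {
    if (layer$type == "slab") {
      delta <- layer$n * k0 * layer$thickness
      Y <- layer$n / Z0
      cd <- cos(delta); sd <- sin(delta)
      a11 <- cd;            a12 <- -1i * sd / Y
      a21 <- -1i * Y * sd;  a22 <- cd
    } else {
      sheet_idx <- sheet_idx + 1
      sig <- if (!is.null(sigma_per_interface))
        rep_len(as.complex(sigma_per_interface[[sheet_idx]]), nf)
      else .sheet_sigma(layer, omega)
      a11 <- one; a12 <- zero; a21 <- sig; a22 <- one
    }
    # right-multiply: M <- M %*% A (fields map input side <- output side)
    t11 <- m11 * a11 + m12 * a21; t12 <- m11 * a12 + m12 * a22
    t21 <- m21 * a11 + m22 * a21; t22 <- m21 * a12 + m22 * a22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  Y0 <- stack$n_in / Z0
  if (stack$pec) {
    # E = 0 on the PEC: state (0, H); r from E_in = M12 H, H_in = M22 H
    den <- Y0 * m12 + m22
    r <- (Y0 * m12 - m22) / den
    Rr <- Mod(r)^2
    Tt <- rep(0, nf)
    t <- rep(0 + 0i, nf)
    A <- 1 - Rr
  } else {
    Ys <- as.complex(stack$backing) / Z0
    den <- Y0 * (m11 + m12 * Ys) + (m21 + m22 * Ys)
    r <- (Y0 * (m11 + m12 * Ys) - (m21 + m22 * Ys)) / den
    t <- 2 * Y0 / den
    Rr <- Mod(r)^2
    Tt <- Re(as.complex(stack$backing)) / Re(stack$n_in) * Mod(t)^2
    A <- 1 - Rr - Tt
  }
  if (any(!is.finite(Rr)))
    stop("non-finite reflectance; check permittivities/conductivities", call. = FALSE)
  structure(list(f_grid = f_grid, R = Rr, T_trans = Tt, A = A, r = r, t = t),
            class = "spectral_response")
}

#' Electrolyte permittivity with the Debye-Falkenhagen ionic correction
#'
#' `eps_sol = eps_H2O + A_DF * sqrt(c_salt)`: the solution permittivity
#' grows with the square root of the ion concentration.
#'
#' @param eps_H2O permittivity of the pure solvent at the frequency band of
#'   interest.
#' @param A_DF coefficient (permittivity per sqrt(mol/m^3)).
#' @param c_salt electrolyte concentration (mol/m^3), >= 0.
#' @return relative permittivity.
#' @export
electrolyte_permittivity <- function(eps_H2O, A_DF, c_salt) {
  if (any(c_salt < 0)) stop("'c_salt' must be non-negative", call. = FALSE)
  eps_H2O + A_DF * sqrt(c_salt)
}

#' Sweep the graphene Fermi level and collect spectra
#'
#' Recomputes the stack response for each Fermi energy (every graphene
#' sheet in the stack is set to that energy) and reports the peak-absorption
#' operating point.
#'
#' @param stack a [layer_stack()] containing at least one graphene sheet
#'   (a [sheet_layer()] holding [graphene_optical_params()]).
#' @param E_f_list Fermi energies (eV), non-empty.
#' @param f_grid frequencies (THz).
#' @return object of class `fermi_sweep`: list of `spectral_response`
#'   (one per `E_f`), plus `E_f_list`, `peak_f` (THz), `peak_A`, and the
#'   argmax entries `E_f_opt`, `A_opt`.
#' @export
fermi_sweep <- function(stack, E_f_list, f_grid) {
  stopifnot(length(E_f_list) >= 1, inherits(stack, "layer_stack"))
  responses <- vector("list", length(E_f_list))
  peak_f <- peak_A <- numeric(length(E_f_list))
  for (i in seq_along(E_f_list)) {
    st <- stack
    st$layers <- lapply(stack$layers, function(l) {
      if (l$type == "sheet" && inherits(l$sigma, "graphene_optical_params"))
        l$sigma$E_f <- E_f_list[i]
      l
    })
    resp <- stack_response(st, f_grid)
    responses[[i]] <- resp
    pk <- find_peak(resp)
    peak_f[i] <- pk$f_r
    peak_A[i] <- pk$A_peak
  }
  iopt <- which.max(peak_A)
  structure(list(responses = responses, E_f_list = E_f_list,
                 peak_f = peak_f, peak_A = peak_A,
                 E_f_opt = E_f_list[iopt], A_opt = peak_A[iopt]),
            class = "fermi_sweep")
}

#' @export
print.spectral_response <- function(x, ...) {
  cat(sprintf("Spectral response: %d points, %.3g-%.3g THz, max A = %.4f at %.3f THz\n",
              length(x$f_grid), min(x$f_grid), max(x$f_grid),
              max(x$A), x$f_grid[which.max(x$A)]))
  invisible(x)
}

#' @export
print.fermi_sweep <- function(x, ...) {
  cat(sprintf("Fermi sweep over %d levels: optimum E_f = %.3g eV (peak A = %.4f)\n",
              length(x$E_f_list), x$E_f_opt, x$A_opt))
  invisible(x)
}

#' @export
as.data.frame.spectral_response <- function(x, ...) {
  data.frame(f_THz = x$f_grid, R = x$R, T = x$T_trans, A = x$A)
}
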