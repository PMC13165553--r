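# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation.

.kc <- list(e = 1.602176634e-19, hbar = 1.054571817e-34, kB = 1.380649e-23,
            eps0 = 8.8541878128e-12, N_A = 6.02214076e23,
            F_const = 96485.33212, R_gas = 8.314462618,
            c0 = 299792458, Z0 = 120 * pi)

# Exact planar Gouy-Chapman potential profile for a symmetric z:z electrolyte:
# tanh(z e phi / 4 kB T) = tanh(z e phi_s / 4 kB T) exp(-x / lambda)
gc_exact_profile <- function(x, phi_s, lambda, T = 300, z = 1) {
  kTze <- .kc$kB * T / (z * .kc$e)
  4 * kTze * atanh(tanh(phi_s / (4 * kTze)) * exp(-x / lambda))
}

# Debye length for a general species set: kappa^-1 with
# kappa^2 = e^2 sum z_i^2 c_i N_A / (eps eps0 kB T)
debye_length_general <- function(z, c_molm3, eps_r, T) {
  k2 <- .kc$e^2 * sum(z^2 * c_molm3 * .kc$N_A) / (eps_r * .kc$eps0 * .kc$kB * T)
  1 / sqrt(k2)
}

# Recursive Airy-summation reflectance, independent of the package's matrix
# cascade. Stack description:
#   media: complex refractive indices of the propagation media in order.
#     PEC backing:       c(n_in, slab_1, ..., slab_M); the mirror (r = -1)
#                        sits behind slab_M. Interfaces: n_in|slab_1, ...,
#                        slab_{M-1}|slab_M -> M of them, sheet sigma[j] each.
#     substrate backing: c(n_in, slab_1, ..., slab_{M}, n_sub); M+1
#                        interfaces, sheet sigma[j] each.
#   d: slab thicknesses, one per medium after the first (excluding n_sub).
#   sigma: sheet conductivity per interface (0 where bare).
# Convention matches exp(-i omega t): phase factor exp(i n k0 d) per pass.
airy_reflectance <- function(media, d, sigma, f_THz, pec = TRUE) {
  k0 <- 2 * pi * f_THz * 1e12 / .kc$c0
  iface <- function(n1, n2, s) {
    den <- n1 + n2 + s * .kc$Z0
    list(r = (n1 - n2 - s * .kc$Z0) / den, t = 2 * n1 / den,
         rp = (n2 - n1 - s * .kc$Z0) / den, tp = 2 * n2 / den)
  }
  K <- length(sigma)  # dielectric interfaces
  recurse <- function(j) {
    if (pec && j == K + 1) return(rep(-1 + 0i, length(k0)))
    io <- iface(media[j], media[j + 1], sigma[j])
    if (!pec && j == K) return(io$r)
    ph2 <- exp(2i * media[j + 1] * k0 * d[j])
    rn <- recurse(j + 1)
    io$r + io$t * io$tp * rn * ph2 / (1 - io$rp * rn * ph2)
  }
  Mod(recurse(1))^2
}

# Gaussian line fixture sharing the spectral_response shape
make_gaussian_fixture <- function(f_r, FWHM, A_peak, f_grid) {
  s <- FWHM / (2 * sqrt(2 * log(2)))
  A <- A_peak * exp(-(f_grid - f_r)^2 / (2 * s^2))
  structure(list(f_grid = f_grid, R = 1 - A, T_trans = rep(0, length(A)), A = A),
            class = "spectral_response")
}
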