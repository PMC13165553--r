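test_that("Helmholtz capacitance matches the parallel-plate form and scalings", {
  expect_equal(helmholtz_capacitance(6, 0.5e-9), 0.1062, tolerance = 1e-3)
  # C proportional to 1/d_H
  expect_equal(helmholtz_capacitance(6, 1.0e-9),
               helmholtz_capacitance(6, 0.5e-9) / 2)
  # vanishing limit for thick layers
  expect_lt(helmholtz_capacitance(1, 1), 1e-10)
  expect_error(helmholtz_capacitance(-1, 1e-9), "positive")
  expect_error(helmholtz_capacitance(6, 0), "positive")
})

test_that("Debye length reproduces the 1 mM value and square-root scaling", {
  lam <- debye_length(1, 78.5, 298)
  expect_equal(lam, 9.6e-9, tolerance = 0.01)
  # textbook rule lambda_D ~ 0.304 nm / sqrt(I[M]) for 1:1 electrolytes
  expect_equal(lam, 0.304e-9 / sqrt(1e-3), tolerance = 0.02)
  expect_equal(debye_length(4, 78.5, 298), lam / 2)
  expect_lt(debye_length(1e9, 78.5, 298), 1e-11)
  expect_error(debye_length(0, 78.5, 298), "positive")
})

test_that("Gouy-Chapman capacitance: zero-potential closed form and symmetry", {
  lam <- debye_length(1, 78.5, 298)
  expect_identical(gouy_chapman_capacitance(1, 0, 78.5, 298),
                   78.5 * physical_constants()$eps0 / lam)
  expect_equal(gouy_chapman_capacitance(1, 0, 78.5, 298), 0.0723, tolerance = 1e-2)
  phis <- c(0.01, 0.05, 0.2, 1)
  expect_equal(gouy_chapman_capacitance(1, phis, 78.5, 298),
               gouy_chapman_capacitance(1, -phis, 78.5, 298))
  # no overflow at extreme potentials
  expect_true(is.finite(gouy_chapman_capacitance(1, 50, 78.5, 298)))
})

test_that("series capacitances combine harmonically and stay below both inputs", {
  expect_equal(stern_series(2, 2), 1)
  expect_equal(stern_series(0.106, 0.0723), 0.0430, tolerance = 2e-3)
  expect_equal(total_capacitance(0.043, 0.0275), 0.01677, tolerance = 2e-3)
  # dominated limit
  expect_equal(stern_series(0.1, 1e12), 0.1, tolerance = 1e-10)
  expect_error(stern_series(0, 1), "positive")
  set.seed(42)
  for (i in 1:50) {
    C1 <- 10^runif(1, -4, 1); C2 <- 10^runif(1, -4, 1)
    expect_lt(stern_series(C1, C2), min(C1, C2))
  }
})

test_that("quantum capacitance: thermal minimum, symmetry, degenerate limit", {
  k <- physical_constants()
  cq0 <- quantum_capacitance_full(0, 300, 1e6)
  expect_equal(cq0, 2 * k$e^2 * k$kB * 300 / (pi * (k$hbar * 1e6)^2) * log(4),
               tolerance = 1e-12)
  expect_equal(cq0, 8.4e-3, tolerance = 1e-2)   # ~0.84 uF/cm^2 Dirac-point floor
  expect_equal(quantum_capacitance_full(0.2, 300), quantum_capacitance_full(-0.2, 300))
  v <- quantum_capacitance_full(seq(0, 0.5, by = 0.05), 300)
  expect_true(all(diff(v) > 0))
  expect_equal(quantum_capacitance_degenerate(1e16), 0.0275, tolerance = 2e-3)
  expect_identical(quantum_capacitance_degenerate(0), 0)
})

test_that("degenerate limit agrees with the full form once e V_ch >= 20 kB T", {
  k <- physical_constants()
  T <- 300
  relerr <- function(n) {
    Vch <- fermi_energy_from_density(n)
    abs(quantum_capacitance_full(Vch, T) - quantum_capacitance_degenerate(n)) /
      quantum_capacitance_degenerate(n)
  }
  kT_eV <- k$kB * T / k$e
  ns <- density_for_fermi_energy(c(20, 25, 30, 40) * kT_eV)
  errs <- vapply(ns, relerr, numeric(1))
  expect_true(all(errs <= 0.02))
  expect_true(all(diff(errs) < 0))   # error shrinks with doping
})

test_that("Fermi energy from density: worked value, scaling, gating prefactor", {
  expect_equal(fermi_energy_from_density(1e16), 0.117, tolerance = 3e-3)
  expect_identical(fermi_energy_from_density(0), 0)
  expect_equal(fermi_energy_from_density(4e16), 2 * fermi_energy_from_density(1e16))
  # with n in cm^-2 and v_f = 1e6 m/s the prefactor is 1.16e-7 eV
  expect_equal(fermi_energy_from_density(cm2_to_m2(1)), 1.16e-7, tolerance = 6e-3)
  # the stated alternative v_f = 1.1e6 m/s gives a distinctly larger prefactor
  expect_equal(fermi_energy_from_density(cm2_to_m2(1), v_f = 1.1e6), 1.28e-7,
               tolerance = 3e-3)
})

test_that("gating energy is monotone and reduces to E_f without interfacial drop", {
  n <- 10^seq(14, 18, by = 0.5)
  expect_equal(gating_energy(n, 1e15), fermi_energy_from_density(n), tolerance = 1e-9)
  Eg <- gating_energy(n, 0.02)
  expect_true(all(diff(Eg) > 0))
  # the quantum-capacitance series combination always enlarges the drop
  C_EDL <- 0.043
  for (ni in n) {
    C_Q <- quantum_capacitance_full(fermi_energy_from_density(ni), 300)
    expect_gt(gating_energy(ni, total_capacitance(C_EDL, C_Q)),
              gating_energy(ni, C_EDL))
  }
})

test_that("gating inversion is the exact inverse of the gating energy", {
  expect_identical(solve_density_for_gating(0, 0.02), 0)
  # C -> infinity reduces to the quadratic inversion of the band term
  n_quad <- solve_density_for_gating(0.3, 1e15)
  pref <- fermi_energy_from_density(cm2_to_m2(1))
  expect_equal(m2_to_cm2(n_quad), (0.3 / pref)^2, tolerance = 1e-6)
  expect_equal(m2_to_cm2(n_quad), 6.7e12, tolerance = 0.02)
  for (n_cm2 in 10^seq(10, 14, by = 1)) {
    n <- cm2_to_m2(n_cm2)
    for (C in c(0.01, 0.043, 1)) {
      Eg <- gating_energy(n, C)
      expect_equal(solve_density_for_gating(Eg, C), n, tolerance = 1e-6)
    }
  }
})

test_that("adsorption maps concentration to carrier density monotonically", {
  pr <- protein_spec(c_bulk = 0)
  ad <- adsorption_model("langmuir")
  expect_equal(carrier_density_from_concentration(pr, ad), ad$n0)
  expect_equal(m2_to_cm2(ad$n0), 6.6e12, tolerance = 0.01)  # E_f = 0.3 eV baseline
  # Langmuir saturation: n -> n0 + |z| Gamma_max
  pr$c_bulk <- 1e9
  expect_equal(carrier_density_from_concentration(pr, ad),
               ad$n0 + 2 * ad$Gamma_max, tolerance = 1e-6)
  cs <- c(0, 0.00118, 0.0118, 0.118, 1.18, 10)
  ns <- vapply(cs, function(cb) {
    pr$c_bulk <- cb; carrier_density_from_concentration(pr, ad)
  }, numeric(1))
  expect_true(all(diff(ns) > 0))
  # linear mode at low concentration
  adl <- adsorption_model("linear", K_ads = 10, Gamma_max = 1e16, n0 = 0)
  pr$c_bulk <- 0.01
  expect_equal(carrier_density_from_concentration(pr, adl), 2 * 1e16 * 10 * 0.01)
})

test_that("screened potential profile has the exponential e-folding structure", {
  lam <- 9.6e-9
  x <- c(0, lam, 2 * lam)
  p <- potential_profile(0.05, lam, x)
  expect_identical(p[1], 0.05)
  expect_equal(p[2], 0.05 / exp(1))
  expect_equal(p[3] / p[2], 1 / exp(1))
  expect_error(potential_profile(0.05, lam, -1e-9), "non-negative")
})

test_that("capacitance set obeys the series inequalities for random electrolytes", {
  set.seed(7)
  for (i in 1:25) {
    el <- electrolyte_spec(c_salt = 10^runif(1, -1, 2), eps_r = runif(1, 40, 78),
                           eps_H = runif(1, 3, 10), d_H = runif(1, 0.3, 1) * 1e-9,
                           T = runif(1, 280, 330))
    cs <- capacitance_set(el, phi = runif(1, -0.2, 0.2), n = 10^runif(1, 14, 17))
    expect_lt(cs$C_EDL, min(cs$C_H, cs$C_GC))
    expect_lt(cs$C_total, min(cs$C_EDL, cs$C_Q))
    expect_true(all(unlist(cs[c("C_H", "C_GC", "C_EDL", "C_Q", "C_total")]) > 0))
  }
})

test_that("unit conversions round-trip to 12 significant figures", {
  x <- c(0.00118, 1.18, 55.7)
  expect_equal(mol_m3_to_g_per_L(g_per_L_to_mol_m3(x, 11800), 11800), x,
               tolerance = 1e-12)
  expect_equal(g_per_L_to_mol_m3(1.18, 11800), 0.1, tolerance = 1e-12)
  n <- c(1e10, 3.7e12, 1e14)
  expect_equal(m2_to_cm2(cm2_to_m2(n)), n, tolerance = 1e-12)
  expect_equal(Fm2_to_uFcm2(0.01), 1)  # 0.01 F/m^2 = 1 uF/cm^2
})
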