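# Finite-volume Poisson-Nernst-Planck solver: discrete operators against
# closed forms, transport against diffusion kernels, and the steady state
# against Debye-Hueckel / Gouy-Chapman theory.

test_that("Poisson solve reproduces closed-form Laplace solutions", {
  # planar, charge-free: linear drop from phi_s to ground
  dom <- pnp_domain("planar", L_or_R = 10e-9, stern_thickness = 0, n_nodes = 64)
  phi <- solve_poisson(0, dom, pnp_boundary("potential", 0.1))
  expect_equal(phi, 0.1 * (1 - dom$xc / 10e-9), tolerance = 1e-12)
  # spherical shell: A + B/r through the boundary values (exact for the
  # shell-harmonic conductances)
  rin <- 1e-9; R <- 4e-9
  dom2 <- pnp_domain("spherical", L_or_R = R, stern_thickness = 0,
                     n_nodes = 64, r_inner = rin)
  phi2 <- solve_poisson(0, dom2, pnp_boundary("potential", 0.05))
  B <- 0.05 / (1 / rin - 1 / R)
  expect_equal(phi2, -B / R + B / dom2$xc, tolerance = 1e-12)
})

test_that("Stern slab enters the surface condition as a series dielectric", {
  # planar, charge-free: compact layer (eps_H, d_H) + diffuse slab in series,
  # so the surface flux equals the two-slab voltage divider
  dH <- 0.5e-9; L <- 10e-9
  dom <- pnp_domain("planar", L_or_R = L, stern_thickness = dH, n_nodes = 200)
  phi <- solve_poisson(0, dom, pnp_boundary("potential", 0.1),
                       eps_r = 78.5, eps_H = 6)
  st <- pnp_init(dom, pnp_species(0, 1e-9, 0), pnp_boundary("potential", 0.1),
                 eps_r = 78.5, eps_H = 6)
  st$phi <- phi
  sig <- surface_charge_from_solution(st)
  k <- physical_constants()
  R_tot <- dH / (6 * k$eps0) + (L - dH) / (78.5 * k$eps0)
  expect_equal(sig, 0.1 / R_tot, tolerance = 1e-10)
})

test_that("field-free transport is pure diffusion with 2 D t variance growth", {
  dom <- pnp_domain("planar", L_or_R = 200e-9, stern_thickness = 0, n_nodes = 200)
  sp <- pnp_species(z = 0, D = 1e-10, c_bulk = 1)
  c0 <- exp(-((dom$xc - 100e-9) / 5e-9)^2 / 2)
  st <- pnp_init(dom, sp, pnp_boundary("potential", 0, outer = "noflux"),
                 conc = matrix(c0))
  for (i in 1:100) st <- step_nernst_planck(st, 2e-9)
  w <- st$conc[, 1] * dom$Vc
  mu <- sum(dom$xc * w) / sum(w)
  v <- sum((dom$xc - mu)^2 * w) / sum(w)
  expect_equal(v, (5e-9)^2 + 2 * 1e-10 * st$t, tolerance = 1e-3)
})

test_that("uniform concentration with no field is an equilibrium", {
  dom <- pnp_domain("planar", L_or_R = 50e-9, stern_thickness = 0, n_nodes = 64)
  sp <- pnp_species(z = c(1, -1), D = c(1e-9, 1e-9), c_bulk = c(2, 2))
  st <- pnp_init(dom, sp, pnp_boundary("potential", 0))
  st2 <- step_nernst_planck(st, 1e-9)
  expect_equal(st2$conc, st$conc, tolerance = 1e-12)
  expect_equal(max(abs(st2$phi)), 0, tolerance = 1e-15)
})

test_that("closed domains conserve mass over long runs", {
  dom <- pnp_domain("planar", L_or_R = 100e-9, stern_thickness = 0, n_nodes = 48)
  sp <- pnp_species(z = -2, D = 1.35e-10, c_bulk = 0.1)  # the protein alone
  st <- pnp_init(dom, sp, pnp_boundary("potential", 0.01, outer = "noflux"))
  m0 <- pnp_total_moles(st)
  for (i in 1:10000) st <- step_nernst_planck(st, 1e-9)
  expect_lt(abs(pnp_total_moles(st) - m0) / m0, 1e-3)
  expect_true(all(st$conc >= 0))
})

test_that("steady state is Boltzmann-distributed and matches Debye-Hueckel", {
  k <- physical_constants()
  lam <- debye_length(1, 78.5, 300)
  dom <- pnp_domain("planar", L_or_R = 16 * lam, stern_thickness = 0, n_nodes = 400)
  sp <- pnp_species(z = c(1, -1), D = c(1e-9, 1e-9), c_bulk = c(1, 1))
  # |z F phi_s / R T| = 0.2 at the edge of the linear regime
  phis <- 0.2 * k$R_gas * 300 / k$F_const
  st <- solve_steady(dom, sp, pnp_boundary("potential", phis), T = 300)
  sel <- dom$xc <= 2 * lam
  dh <- phis * exp(-dom$xc / lam)
  expect_lt(max(abs(st$phi[sel] - dh[sel]) / abs(dh[sel])), 0.05)
  # Boltzmann identity at convergence, all species
  for (j in 1:2)
    expect_equal(log(st$conc[, j] / sp$c_bulk[j]),
                 -sp$z[j] * k$F_const * st$phi / (k$R_gas * 300),
                 tolerance = 1e-9)
  # zero drive: flat everything
  st0 <- solve_steady(dom, sp, pnp_boundary("potential", 0), T = 300)
  expect_equal(max(abs(st0$phi)), 0, tolerance = 1e-15)
  expect_equal(st0$conc, matrix(rep(c(1, 1), each = 400), ncol = 2),
               ignore_attr = TRUE)
})

test_that("valence enters only through z: the +-2 system matches its own theory", {
  # divalent symmetric pair at small potential: Debye-Hueckel with
  # kappa^2 scaled by z^2 = 4
  k <- physical_constants()
  lam2 <- debye_length_general(c(2, -2), c(0.25, 0.25), 78.5, 300)
  dom <- pnp_domain("planar", L_or_R = 16 * lam2, stern_thickness = 0, n_nodes = 400)
  sp <- pnp_species(z = c(2, -2), D = c(1e-9, 1.35e-10), c_bulk = c(0.25, 0.25))
  phis <- 0.1 * k$R_gas * 300 / (2 * k$F_const)   # |z F phi/RT| = 0.1
  st <- solve_steady(dom, sp, pnp_boundary("potential", phis), T = 300)
  sel <- dom$xc <= 2 * lam2
  dh <- phis * exp(-dom$xc / lam2)
  expect_lt(max(abs(st$phi[sel] - dh[sel]) / abs(dh[sel])), 0.05)
})

test_that("surface charge readout matches the linearized double-layer capacitor", {
  k <- physical_constants()
  lam <- debye_length(1, 78.5, 300)
  dom <- pnp_domain("planar", L_or_R = 16 * lam, stern_thickness = 0, n_nodes = 400)
  sp <- pnp_species(z = c(1, -1), D = c(1e-9, 1e-9), c_bulk = c(1, 1))
  phis <- 2e-3
  st <- solve_steady(dom, sp, pnp_boundary("potential", phis), T = 300)
  sig <- surface_charge_from_solution(st)
  expect_equal(sig, 78.5 * k$eps0 * phis / lam, tolerance = 0.05)
  expect_gt(sig * phis, 0)  # same sign as the electrode potential
  st0 <- solve_steady(dom, sp, pnp_boundary("potential", 0), T = 300)
  expect_equal(surface_charge_from_solution(st0), 0, tolerance = 1e-18)
  # numeric differential capacitance at phi_s -> 0 equals eps eps0 / lambda_D
  stm <- solve_steady(dom, sp, pnp_boundary("potential", -phis), T = 300)
  dC <- (sig - surface_charge_from_solution(stm)) / (2 * phis)
  expect_equal(dC, 78.5 * k$eps0 / lam, tolerance = 0.05)
})

test_that("transient solution relaxes to the steady state", {
  lam <- debye_length(1, 78.5, 300)
  L <- 8 * lam
  dom <- pnp_domain("planar", L_or_R = L, stern_thickness = 0, n_nodes = 128)
  sp <- pnp_species(z = c(1, -1), D = c(1e-9, 1e-9), c_bulk = c(1, 1))
  bc <- pnp_boundary("potential", 0.025)
  ss <- solve_steady(dom, sp, bc, T = 300)
  tr <- pnp_init(dom, sp, bc)
  tau <- lam^2 / 1e-9
  for (i in 1:240) tr <- step_nernst_planck(tr, tau / 2)
  expect_lt(max(abs(tr$phi - ss$phi)) / max(abs(ss$phi)), 1e-3)
  expect_lt(max(abs(tr$conc - ss$conc)) / max(ss$conc), 5e-3)
})

test_that("surface-charge boundary condition is the dual of fixed potential", {
  lam <- debye_length(1, 78.5, 300)
  dom <- pnp_domain("planar", L_or_R = 16 * lam, stern_thickness = 0, n_nodes = 300)
  sp <- pnp_species(z = c(1, -1), D = c(1e-9, 1e-9), c_bulk = c(1, 1))
  stv <- solve_steady(dom, sp, pnp_boundary("potential", 0.01), T = 300)
  sig <- surface_charge_from_solution(stv)
  stq <- solve_steady(dom, sp, pnp_boundary("charge", sig), T = 300)
  expect_equal(stq$phi, stv$phi, tolerance = 1e-6)
})
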