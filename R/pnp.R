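# 1-D Poisson-Nernst-Planck solver for the diffuse layer outside a charge-free
# Stern compact layer, on planar and spherical (radially symmetric) domains.
#
# Discretization: cell-centred finite volumes with Scharfetter-Gummel
# (exponential-fitting) fluxes for the drift-diffusion transport, which keeps
# concentrations positive and reproduces constant-flux limits exactly.
# Steady state: damped Newton on the Poisson-Boltzmann residual (the fixed
# point where every flux vanishes and species are Boltzmann-distributed,
# self-consistent with Poisson). Transient: implicit Euler, species solves
# lagged one Gummel sweep behind the potential. Everything is deterministic.

#' Computational domain for the diffuse-layer solver
#'
#' The mesh covers the electrolyte between the compact/diffuse boundary and
#' the outer boundary. The compact (Stern) layer is charge-free and enters
#' only as a series dielectric slab of thickness `stern_thickness` and
#' permittivity `eps_H` in the surface boundary condition. For the spherical
#' geometry the default extent matches a 4 nm electrolyte droplet.
#'
#' @param geometry `"planar"` or `"spherical"`.
#' @param L_or_R outer extent of the electrolyte domain (m).
#' @param stern_thickness compact-layer thickness (m). The diffuse domain
#'   starts just outside it: at `x = stern_thickness` (planar, electrode at
#'   `x = 0`) or at `r = r_inner + stern_thickness` (spherical, electrode
#'   sphere of radius `r_inner`).
#' @param n_nodes number of finite-volume cells (>= 16).
#' @param grading `"uniform"` or `"geometric"` (cells refined toward the
#'   surface with ratio `grading_ratio`).
#' @param grading_ratio total coarsening factor from first to last cell when
#'   `grading = "geometric"`.
#' @param r_inner electrode radius for the spherical geometry (m).
#' @return object of class `pnp_domain` carrying the face coordinates `xf`,
#'   cell centres `xc`, cell volumes `Vc` (per steradian for spherical),
#'   the geometric conductance factors used by the discrete operators, and
#'   the geometry metadata.
#' @export
pnp_domain <- function(geometry = c("planar", "spherical"), L_or_R = 4e-9,
                       stern_thickness = 0.5e-9, n_nodes = 128,
                       grading = c("uniform", "geometric"),
                       grading_ratio = 8, r_inner = 0.5e-9) {
  geometry <- match.arg(geometry)
  grading <- match.arg(grading)
  if (n_nodes < 16) stop("'n_nodes' must be >= 16", call. = FALSE)
  if (stern_thickness < 0) stop("'stern_thickness' must be >= 0", call. = FALSE)
  x0 <- if (geometry == "planar") stern_thickness else r_inner + stern_thickness
  if (geometry == "spherical" && r_inner <= 0)
    stop("spherical geometry needs r_inner > 0", call. = FALSE)
  if (L_or_R <= x0)
    stop("domain extent L_or_R must exceed the compact-layer boundary", call. = FALSE)
  if (grading == "uniform") {
    xf <- seq(x0, L_or_R, length.out = n_nodes + 1)
  } else {
    # geometric cell widths h_i = h_1 * q^(i-1), total ratio grading_ratio
    q <- grading_ratio^(1 / (n_nodes - 1))
    w <- q^(0:(n_nodes - 1))
    w <- w / sum(w) * (L_or_R - x0)
    xf <- x0 + c(0, cumsum(w))
  }
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  n <- n_nodes
  if (geometry == "planar") {
    Vc <- diff(xf)
    A_surf <- 1
    gf_int <- 1 / diff(xc)                     # face conductance / (eps eps0 or D)
    gf_L <- 1 / (xc[1] - xf[1])
    gf_R <- 1 / (xf[n + 1] - xc[n])
    gf_stern <- if (stern_thickness > 0) 1 / stern_thickness else Inf
  } else {
    Vc <- diff(xf^3) / 3
    A_surf <- xf[1]^2
    # exact shell-harmonic conductances: flux = g * dphi is exact for A + B/r
    gf_int <- 1 / (1 / xc[-n] - 1 / xc[-1])
    gf_L <- 1 / (1 / xf[1] - 1 / xc[1])
    gf_R <- 1 / (1 / xc[n] - 1 / xf[n + 1])
    gf_stern <- if (stern_thickness > 0)
      1 / (1 / r_inner - 1 / (r_inner + stern_thickness)) else Inf
  }
  structure(list(geometry = geometry, L_or_R = L_or_R,
                 stern_thickness = stern_thickness, r_inner = r_inner,
                 n_nodes = n_nodes, grading = grading,
                 xf = xf, xc = xc, Vc = Vc, A_surf = A_surf,
                 gf_int = gf_int, gf_L = gf_L, gf_R = gf_R,
                 gf_stern = gf_stern),
            class = "pnp_domain")
}

#' Mobile species set for the PNP solver
#'
#' @param z valences (one per species).
#' @param D diffusivities (m^2/s, one per species).
#' @param c_bulk bulk concentrations (mol/m^3, one per species).
#' @param names optional species labels.
#' @return object of class `pnp_species`.
#' @export
pnp_species <- function(z, D, c_bulk, names = NULL) {
  k <- length(z)
  stopifnot(length(D) == k, length(c_bulk) == k, all(D > 0), all(c_bulk >= 0))
  if (is.null(names)) names <- paste0("species", seq_len(k))
  net <- sum(z * c_bulk)
  if (abs(net) > 1e-12 * max(sum(abs(z) * c_bulk), 1e-300) && k > 1)
    warning("bulk is not electroneutral: sum(z_i c_i) = ", signif(net, 3),
            " mol/m^3", call. = FALSE)
  structure(list(z = z, D = D, c_bulk = c_bulk, names = names, n_species = k),
            class = "pnp_species")
}

#' Boundary conditions for the PNP solver
#'
#' Exactly one surface condition is active at the graphene/Stern interface:
#' a fixed surface potential `phi_s` (applied at the graphene plane; the
#' charge-free Stern slab is folded in as a series dielectric) or a fixed
#' surface charge density (C/m^2). The outer boundary is either grounded
#' with bulk Dirichlet concentrations (`outer = "dirichlet"`) or closed
#' (`outer = "noflux"`, species conserved; the potential stays grounded).
#'
#' @param surface `"potential"` or `"charge"`.
#' @param value surface potential (V) or surface charge (C/m^2).
#' @param outer `"dirichlet"` or `"noflux"`.
#' @return object of class `pnp_boundary`.
#' @export
pnp_boundary <- function(surface = c("potential", "charge"), value = 0,
                         outer = c("dirichlet", "noflux")) {
  surface <- match.arg(surface)
  outer <- match.arg(outer)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(surface = surface, value = value, outer = outer),
            class = "pnp_boundary")
}

# Thomas algorithm for tridiagonal systems: lower a (n-1), diag b (n),
# upper c (n-1), rhs d.
.thomas <- function(a, b, cc, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m <- b[i] - a[i - 1] * cp[i - 1]
      cp[i] <- cc[i] / m
      dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / m
    }
  }
  m <- b[n] - a[n - 1] * cp[n - 1]
  dp[n] <- (d[n] - a[n - 1] * dp[n - 1]) / m
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Coupling coefficients for the Poisson operator: interior and boundary
# face conductances from the domain's geometric factors. The charge-free
# Stern slab enters in series at the surface face when present.
.poisson_coeffs <- function(domain, eps_r, eps_H) {
  eps0 <- .const$eps0
  g_int <- eps_r * eps0 * domain$gf_int
  gL_diffuse <- eps_r * eps0 * domain$gf_L
  if (is.finite(domain$gf_stern)) {
    gL_stern <- eps_H * eps0 * domain$gf_stern
    gL <- 1 / (1 / gL_diffuse + 1 / gL_stern)
  } else gL <- gL_diffuse
  gR <- eps_r * eps0 * domain$gf_R
  list(g_int = g_int, gL = gL, gR = gR)
}

#' Solve the 1-D Poisson equation on the diffuse-layer domain
#'
#' Discrete solution of `div(eps eps0 grad phi) = -rho` in planar or
#' radially-symmetric spherical coordinates, second-order accurate on
#' smooth meshes. In the compact layer (zero charge) the same operator
#' reduces to Laplace and is folded in as a series dielectric.
#'
#' @param rho charge density (C/m^3) at the cell centres (scalar recycled).
#' @param domain a [pnp_domain()].
#' @param bc a [pnp_boundary()].
#' @param eps_r diffuse-layer relative permittivity.
#' @param eps_H compact-layer relative permittivity (used only when
#'   `stern_thickness > 0` and the surface condition is a potential).
#' @return potential (V) at the cell centres.
#' @export
solve_poisson <- function(rho, domain, bc, eps_r = 78.5, eps_H = 6) {
  stopifnot(inherits(domain, "pnp_domain"), inherits(bc, "pnp_boundary"))
  n <- domain$n_nodes
  rho <- rep_len(rho, n)
  co <- .poisson_coeffs(domain, eps_r, eps_H)
  lower <- -co$g_int
  upper <- -co$g_int
  diag_ <- c(co$g_int, 0) + c(0, co$g_int)
  rhs <- rho * domain$Vc
  if (bc$surface == "potential") {
    diag_[1] <- diag_[1] + co$gL
    rhs[1] <- rhs[1] + co$gL * bc$value
  } else {
    # fixed surface charge sigma: inward displacement flux sigma * area
    rhs[1] <- rhs[1] + bc$value * domain$A_surf
  }
  # outer boundary: grounded in both modes (no-flux applies to species only)
  diag_[n] <- diag_[n] + co$gR
  if (any(!is.finite(rhs)) || any(!is.finite(diag_)))
    stop("singular or ill-posed Poisson system", call. = FALSE)
  .thomas(lower, diag_, upper, rhs)
}

# Bernoulli function B(x) = x / (exp(x) - 1), stable near 0 and for large |x|.
.bernoulli <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-10
  out[small] <- 1 - x[small] / 2
  xs <- x[!small]
  out[!small] <- ifelse(xs > 500, 0,
                        ifelse(xs < -500, -xs, xs / expm1(xs)))
  out
}

# One implicit-Euler Scharfetter-Gummel step for a single species.
# Returns the new concentration field; matrix is an M-matrix so positivity
# is preserved for any dt.
.sg_step <- function(c_old, z, D, c_bulk, phi, domain, bc, T, dt) {
  n <- domain$n_nodes
  FT <- .const$F_const / (.const$R_gas * T)
  u <- z * FT * diff(phi)                       # across interior faces
  k_int <- D * domain$gf_int
  Bp <- .bernoulli(u); Bm <- .bernoulli(-u)
  # J_{i+1/2} = k (B(u) c_i - B(-u) c_{i+1}), positive from i to i+1
  lower <- -k_int * Bp
  upper <- -k_int * Bm
  diag_ <- numeric(n)
  diag_ <- c(k_int * Bp, 0) + c(0, k_int * Bm)
  rhs <- domain$Vc * c_old / dt
  diag_ <- diag_ + domain$Vc / dt
  # surface: blocking electrode, zero flux (nothing to add)
  # outer: Dirichlet bulk via ghost at the boundary face (phi = 0 there)
  if (bc$outer == "dirichlet") {
    uR <- z * FT * (0 - phi[n])
    kR <- D * domain$gf_R
    diag_[n] <- diag_[n] + kR * .bernoulli(uR)
    rhs[n] <- rhs[n] + kR * .bernoulli(-uR) * c_bulk
  }
  .thomas(lower, diag_, upper, rhs)
}

#' Advance the coupled Nernst-Planck/Poisson system one time step
#'
#' Implicit-Euler Scharfetter-Gummel update of every species against the
#' current potential, followed by a Poisson re-solve with the updated charge
#' density. Concentrations remain non-negative by construction (the
#' transport matrix is an M-matrix); if a negative value nevertheless
#' appears the step is rejected and retried with `dt/2`, up to 20 times.
#'
#' @param state a `pnp_state` as returned by [pnp_init()] or a previous step.
#' @param dt time step (s).
#' @return updated `pnp_state` with `t` advanced by `dt`.
#' @export
step_nernst_planck <- function(state, dt) {
  stopifnot(inherits(state, "pnp_state"), dt > 0)
  dom <- state$domain; sp <- state$species; bc <- state$bc
  for (attempt in 1:20) {
    cnew <- state$conc
    ok <- TRUE
    for (j in seq_len(sp$n_species)) {
      cj <- .sg_step(state$conc[, j], sp$z[j], sp$D[j], sp$c_bulk[j],
                     state$phi, dom, bc, state$T, dt)
      if (any(cj < -1e-12 * max(abs(cj), 1e-300))) { ok <- FALSE; break }
      cnew[, j] <- pmax(cj, 0)
    }
    if (ok) {
      rho <- .const$F_const * as.numeric(cnew %*% sp$z)
      phi <- solve_poisson(rho, dom, bc, state$eps_r, state$eps_H)
      state$conc <- cnew
      state$phi <- phi
      state$rho <- rho
      state$t <- state$t + dt
      return(state)
    }
    dt <- dt / 2
  }
  stop("time step repeatedly produced negative concentrations", call. = FALSE)
}

#' Initialize a transient PNP state
#'
#' Species start at their bulk concentrations (or a supplied field) and the
#' potential solves Poisson for that charge density.
#'
#' @param domain a [pnp_domain()].
#' @param species a [pnp_species()].
#' @param bc a [pnp_boundary()].
#' @param T temperature (K).
#' @param eps_r,eps_H diffuse- and compact-layer relative permittivities.
#' @param conc optional initial concentration matrix (n_nodes x n_species).
#' @return object of class `pnp_state` with fields `t`, `phi`, `rho`, `E`
#'   (field at faces, V/m), `conc`, and the configuration.
#' @export
pnp_init <- function(domain, species, bc, T = 300, eps_r = 78.5, eps_H = 6,
                     conc = NULL) {
  n <- domain$n_nodes
  if (is.null(conc))
    conc <- matrix(rep(species$c_bulk, each = n), nrow = n)
  stopifnot(nrow(conc) == n, ncol(conc) == species$n_species, all(conc >= 0))
  rho <- .const$F_const * as.numeric(conc %*% species$z)
  phi <- solve_poisson(rho, domain, bc, eps_r, eps_H)
  st <- structure(list(t = 0, phi = phi, rho = rho, conc = conc,
                       domain = domain, species = species, bc = bc,
                       T = T, eps_r = eps_r, eps_H = eps_H,
                       converged = NA, iterations = NA_integer_,
                       residual = NA_real_),
                  class = "pnp_state")
  st
}

#' Steady state of the PNP system (Poisson-Boltzmann fixed point)
#'
#' With a grounded Dirichlet outer boundary the stationary state of the
#' Nernst-Planck equations has vanishing fluxes, i.e. every species is
#' Boltzmann-distributed, `c_i = c_bulk_i exp(-z_i F phi / (R T))`,
#' self-consistently with Poisson. That nonlinear problem is solved by
#' damped Newton iteration on the potential (halving line search on the
#' residual norm), iterating until the maximum potential update falls below
#' `tol * max(1, |phi_s|)`.
#'
#' @param domain a [pnp_domain()].
#' @param species a [pnp_species()].
#' @param bc a [pnp_boundary()]; both surface condition types are supported.
#' @param T temperature (K).
#' @param eps_r,eps_H diffuse- and compact-layer relative permittivities.
#' @param tol relative convergence tolerance on the potential update.
#' @param max_iter maximum outer iterations.
#' @return converged `pnp_state` (fields as in [pnp_init()], plus
#'   `converged`, `iterations`, `residual`).
#' @export
solve_steady <- function(domain, species, bc, T = 300, eps_r = 78.5,
                         eps_H = 6, tol = 1e-8, max_iter = 200) {
  stopifnot(tol > 0)
  n <- domain$n_nodes
  FT <- .const$F_const / (.const$R_gas * T)
  co <- .poisson_coeffs(domain, eps_r, eps_H)
  scale <- max(1, abs(bc$value))
  boltz <- function(phi) {
    ex <- exp(pmin(pmax(-outer(phi, species$z) * FT, -50), 50))
    sweep(ex, 2, species$c_bulk, `*`)       # n x k concentrations
  }
  resid <- function(phi) {
    cc <- boltz(phi)
    rho <- .const$F_const * as.numeric(cc %*% species$z)
    # flux form of div(eps eps0 grad phi) + rho over each cell
    fl <- co$g_int * (phi[-1] - phi[-n])    # displacement flux into cell i from the right
    r <- c(fl, 0) + c(0, -fl)
    if (bc$surface == "potential") r[1] <- r[1] + co$gL * (bc$value - phi[1])
    else r[1] <- r[1] + bc$value * domain$A_surf
    r[n] <- r[n] + co$gR * (0 - phi[n])
    r + rho * domain$Vc
  }
  phi <- rep(0, n)
  rnorm0 <- NULL
  it <- 0
  repeat {
    it <- it + 1
    cc <- boltz(phi)
    # Jacobian of resid: tridiag(-g) minus diag(V * F^2/RT * sum z^2 c)
    lower <- co$g_int
    upper <- co$g_int
    diag_ <- -(c(co$g_int, 0) + c(0, co$g_int)) - domain$Vc * .const$F_const *
      FT * as.numeric(cc %*% (species$z^2))
    if (bc$surface == "potential") diag_[1] <- diag_[1] - co$gL
    diag_[n] <- diag_[n] - co$gR
    r <- resid(phi)
    rn <- sqrt(sum(r^2))
    if (is.null(rnorm0)) rnorm0 <- max(rn, 1e-300)
    dphi <- .thomas(lower, diag_, upper, -r)
    # damped update: halve until the residual norm does not increase
    alpha <- 1
    for (ls in 1:30) {
      phin <- phi + alpha * dphi
      if (sqrt(sum(resid(phin)^2)) <= rn * (1 + 1e-12)) break
      alpha <- alpha / 2
    }
    upd <- max(abs(alpha * dphi))
    phi <- phi + alpha * dphi
    if (upd <= tol * scale) break
    if (it >= max_iter)
      stop(sprintf("steady PNP solve did not converge in %d iterations (max update %.3g V, residual %.3g)",
                   max_iter, upd, rn / rnorm0), call. = FALSE)
  }
  conc <- boltz(phi)
  st <- pnp_init(domain, species, bc, T, eps_r, eps_H, conc = conc)
  st$phi <- phi
  st$rho <- .const$F_const * as.numeric(conc %*% species$z)
  st$converged <- TRUE
  st$iterations <- it
  st$residual <- sqrt(sum(resid(phi)^2)) / rnorm0
  st
}

#' Surface charge density from a converged PNP solution
#'
#' Gauss-law readout at the compact/diffuse boundary:
#' `sigma = eps eps0 E(0+)` with `E = -dphi/dx`, evaluated from the
#' boundary-face displacement flux (through the Stern slab when present).
#' In the linearized planar regime this equals `eps_r eps0 phi_s / lambda_D`.
#' The sign matches the electrode potential (the diffuse-layer countercharge
#' is its negative).
#'
#' @param state a `pnp_state`.
#' @return surface charge density (C/m^2).
#' @export
surface_charge_from_solution <- function(state) {
  stopifnot(inherits(state, "pnp_state"))
  bc <- state$bc
  if (bc$surface == "charge") return(bc$value)
  co <- .poisson_coeffs(state$domain, state$eps_r, state$eps_H)
  co$gL * (bc$value - state$phi[1]) / state$domain$A_surf
}

#' Total moles of each species in the domain
#' @param state a `pnp_state`.
#' @return numeric vector (mol per unit area, or per steradian for spherical).
#' @export
pnp_total_moles <- function(state) {
  as.numeric(crossprod(state$conc, state$domain$Vc))
}

#' Electric field at the cell faces
#' @param state a `pnp_state`.
#' @return `E = -dphi/dx` (V/m) at interior faces.
#' @export
pnp_field <- function(state) {
  -diff(state$phi) / diff(state$domain$xc)
}

#' @export
print.pnp_state <- function(x, ...) {
  cat(sprintf("PNP state (%s, %d cells): t = %.3g s, phi range [%.3g, %.3g] V\n",
              x$domain$geometry, x$domain$n_nodes, x$t,
              min(x$phi), max(x$phi)))
  if (isTRUE(x$converged))
    cat(sprintf("  steady solve: %d iterations, relative residual %.3g\n",
                x$iterations, x$residual))
  invisible(x)
}
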