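---
title: "Modelling an electrolyte-gated graphene perfect-absorber SPR biosensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an electrolyte-gated graphene perfect-absorber SPR biosensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapheneSPR)
```

## The device and the model chain

The device is a terahertz perfect absorber whose active element is
electrolyte-gated graphene. A charged analyte protein (β2-microglobulin,
modelled as a mobile species of valence −2, effective diameter 4 nm,
self-diffusion coefficient 1.35×10⁻¹⁰ m²/s, molar mass 11.8 kg/mol) adsorbs
near the graphene surface, perturbs the interfacial charge balance, shifts
the graphene Fermi level, and thereby moves the absorption resonance of a
PEC-backed layer stack. Reading the resonance shift against concentration
gives the sensor characteristics.

The package implements this chain as four composable stages:

1. electrostatics of the electric double layer (EDL) with graphene quantum
   capacitance (`helmholtz_capacitance()`, `gouy_chapman_capacitance()`,
   `stern_series()`, `quantum_capacitance_full()`, `gating_energy()`, ...);
2. a 1-D Poisson–Nernst–Planck (PNP) solver for the diffuse layer
   (`solve_steady()`, `step_nernst_planck()`), used to examine the field and
   concentration profiles the compact closed forms summarize;
3. graphene sheet conductivity and thin-film optics
   (`graphene_conductivity()`, `stack_response()`, `fermi_sweep()`);
4. resonance feature extraction and the six performance metrics
   (`find_peak()`, `compute_metrics()`, `run_sweep()`,
   `estimate_lod_baseline()`).

## The gating relation, and why quantum capacitance amplifies the response

A sheet density $n$ on graphene costs the band-filling energy
$E_f(n) = \hbar v_f \sqrt{\pi n}/e$ (in eV) *and* the electrostatic drop
across the interfacial capacitance, $\varphi = n e / C$. We call their sum
the gating energy,

$$E_g = \frac{\hbar v_f \sqrt{\pi n}}{e} + \frac{n e}{C},$$

and take $E_g$ — the electrochemical potential of the gated graphene — as
the operating level that enters the optical conductivity in the sensing
chain. With $v_f = 10^6$ m/s and $n$ in cm⁻² the band term is
$1.17\times10^{-7}\sqrt{n}$ eV; `solve_density_for_gating()` inverts the
relation exactly (bracketed root finding, residual below 10⁻⁹ eV).

Two capacitance modes are supported. The Stern mode uses
$C = C_{EDL} = (C_H^{-1} + C_{GC}^{-1})^{-1}$. The quantum-capacitance mode
uses $C = (C_{EDL}^{-1} + C_Q^{-1})^{-1}$. Since the series combination is
always smaller than $C_{EDL}$, the interfacial term $ne/C$ — and hence the
swing of $E_g$ with adsorbed charge — is always larger in the second mode:
this is the model's expression of the claim that neglecting quantum
capacitance underestimates the gating response. Near the operating point
($E_f \approx 0.3$ eV, $n_0 \approx 6.6\times10^{12}$ cm⁻²) $C_Q$ is a few
µF/cm², comparable to $C_{EDL}$, so the correction is far from marginal.

The mapping from bulk concentration to induced density is an adsorption
isotherm (`carrier_density_from_concentration()`): Langmuir by default,
$n = n_0 + |z_p|\,\Gamma_{max}\,K c/(1+Kc)$, with $K = 10$ L/g and
$\Gamma_{max} = 10^{16}$ m⁻². The functional form is a modelling choice —
the physical statement being represented is only that adsorption links bulk
concentration to an effective surface charge, monotonically and with
saturation. $K$ was set so that the four study concentrations
(0.00118–1.18 g/L) straddle the knee of the isotherm: the two lowest sit in
the near-linear regime and the highest is close to saturation, which is
what makes the low-concentration sensitivity orders of magnitude larger
than the high-concentration one. $n_0$ defaults to the density whose Fermi
energy is 0.3 eV, the absorber's optimal doping.

## Electrostatic parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `c_salt` | 1 | mol/m³ | 1 mM background, dilute-electrolyte regime where Gouy–Chapman applies |
| `eps_r` | 78.5 | – | static permittivity of water in the diffuse layer |
| `eps_H` | 6 | – | strongly oriented water in the compact layer |
| `d_H` | 0.5 | nm | solvated-ion radius |
| `T` | 300 | K | matches the protein transport data |
| `v_f` | 1.0×10⁶ | m/s | reproduces the 1.16×10⁻⁷ eV gating prefactor; the alternative 1.1×10⁶ (prefactor 1.28×10⁻⁷) is configurable |
| `z_p`, `D_p`, diameter, M | −2, 1.35×10⁻¹⁰ m²/s, 4 nm, 11.8 kDa | | protein constants, taken as fixed inputs |

The compact-layer values (`eps_H`, `d_H`) are conventional aqueous numbers;
they are not measured properties of this device and every one of them is a
configuration key.

## The PNP solver

The diffuse layer outside a charge-free Stern slab is discretized by
cell-centred finite volumes on planar or spherical 1-D domains, with
Scharfetter–Gummel (exponential-fitting) fluxes for every species. This
choice is deliberate: SG fluxes keep concentrations non-negative for any
time step (the transport matrix is an M-matrix), reduce to central
differences for weak fields, and are exact for constant-flux profiles. For
the spherical geometry the face conductances use the exact shell-harmonic
form $1/(1/r_i - 1/r_{i+1})$, which makes charge-free solutions
($A + B/r$) exact on any mesh.

The steady state solves the Poisson–Boltzmann fixed point (all fluxes zero,
species Boltzmann-distributed self-consistently with Poisson) by damped
Newton iteration: tridiagonal Jacobian, residual-halving line search,
convergence when the maximum potential update falls below a relative 10⁻⁸
(at most 200 iterations; Boltzmann exponents are clamped at ±50 to avoid
overflow during intermediate iterates). The transient path advances each
species implicitly (Thomas solves) against the current potential, then
re-solves Poisson; a step producing a negative concentration is rejected
and retried at half the step, although the M-matrix property makes that a
degenerate safeguard. Because the potential is lagged one step, the
*coupled* charging dynamics are stable for steps up to about the Debye
relaxation time $\lambda_D^2/D$; the test suite uses half that.

Verification anchors (all in the test suite): planar/spherical Laplace
closed forms; the diffusion-kernel variance growth $2Dt$; mass conservation
in closed domains over 10⁴ steps; the Debye–Hückel profile
$\varphi_0 e^{-x/\lambda_D}$ within 5% for surface potentials with
$|zF\varphi_s/RT| \le 0.2$; second-order spatial convergence (order ≥ 1.9
in L2, grids of 64–256 cells) against the exact nonlinear Gouy–Chapman
profile of a symmetric electrolyte; and agreement between the
fixed-potential and fixed-charge boundary formulations. The droplet-scale
default (spherical, R = 4 nm, the protein as the sole mobile species at its
molar concentration) treats a volume that barely contains one protein as a
continuum — a deliberate idealization inherited from the device concept;
the planar domain with background salt is the configuration the
quantitative checks use.

## Optics

The graphene sheet conductivity is the Kubo/RPA result: the intraband
(Drude-like) term with $\ln[2\cosh(E_f/2k_BT)]$ weight, and the interband
term in the standard $2E_f$ form with the Pauli-blocking edge at
$\hbar\omega = 2E_f$ and the universal limit $e^2/4\hbar$. A variant
spelling of the interband formula that circulates with $E_f$ in place of
$2E_f$ and a stray additive $1/\pi$ is implemented behind
`form = "printed"` for comparison; it is not the default because it
violates the universal-conductivity and Pauli-blocking limits.
The relaxation time defaults to $\tau = 10^{-13}$ s, typical of CVD
graphene.

The stack response is the exact 2×2 characteristic-matrix cascade at normal
incidence with zero-thickness conductive-sheet jump conditions, under the
$e^{-i\omega t}$ convention (lossy media have $\mathrm{Im}\,n \ge 0$,
passive sheets $\mathrm{Re}\,\sigma \ge 0$). With a PEC backing the
transmission channel is removed identically and $A = 1 - R$ holds to
machine precision by construction. The implementation is checked to 10⁻¹⁰
against an independently coded recursive Airy summation and against the
classical Salisbury-screen closed form (sheet of resistance $Z_0$ a
quarter-wave above a mirror: $R = 0$ at the design frequency).

### The default stack and its trade-off

The default absorber is electrolyte / graphene / spacer (ε = 3.9, 10 µm) /
graphene / PEC. Two of its numbers deserve comment.

*Electrolyte permittivity.* The Debye–Falkenhagen correction
$\varepsilon_{sol} = \varepsilon_{H_2O} + A\sqrt{c}$ is applied to the
THz-band water permittivity (default 4.2), not to the static 78.5: at
0.1–10 THz the orientational relaxation of water is fully relaxed, and a
superstrate index of ~8.9 would both be unphysical and mismatch the
absorber so badly that peak absorption stays below 10%. The static values
remain in force in the electrostatic module, where they belong.

*Spacer thickness.* The quarter-wave frequency of the 10 µm spacer is
~3.8 THz; the inductive graphene sheet pushes the resonance above it, and
increasing the Fermi level pushes it further up — the blueshift the sensor
reads out. The resonance position as a function of gating energy is
concave: it rises steeply near low doping and saturates at high doping. A
thicker spacer (lower resonance, better impedance match to the graphene
sheet conductance) gives deeper absorption — about 0.97 peak absorption at
40 µm — but parks the operating point on the saturated branch, where the
larger gating swing of the quantum-capacitance mode no longer translates
into a larger frequency shift. The shipped 10 µm default keeps the
operating point on the rising branch, so that the quantum-capacitance mode
shifts strictly further for every concentration pair (peak absorption at
the baseline is then ~0.5). Users who want the deep-absorption regime set
`stack$spacer_thickness` accordingly and accept the inverted mode ordering.

The frequency grid defaults to 0.1–10 THz with 2000 points; `find_peak()`
warns if fewer than 20 samples span the extracted FWHM.

## Feature extraction and metrics

`find_peak()` refines the discrete absorption maximum by a parabola through
the three surrounding samples and takes the FWHM from linearly interpolated
half-maximum crossings nearest the peak; a peak whose half-maximum is not
bracketed inside the grid is an error, not a guess. Structure entirely
below the half-maximum level (a pedestal in the far wings) cannot move
either feature. Flat or degenerate sample triples fall back to the discrete
maximum.

`compute_metrics()` evaluates S, FOM, Q, SNR, DA, LOD. The identities
FOM = S·DA, SNR = Δf·DA and Q = f_r·DA are enforced by construction
(everything is derived from one DA = 1/FWHM), not merely tested. The FWHM
and $f_r$ entering DA and Q are taken from the higher-concentration
spectrum of each pair — a convention that must be fixed somewhere; metrics
are reported both pairwise and against the lowest concentration as
baseline, since either convention for Δf is defensible. Zero sensitivity
yields an infinite LOD with a warning rather than an error.

## Synthetic data and the noise model

Two synthetic generators exist, and they are the only sources of randomness
in the package:

- `make_lorentzian_fixture()` produces an analytic Lorentzian absorption
  line (optionally with seeded multiplicative Gaussian noise) in the same
  container as a computed spectrum. It underpins the feature-extraction
  tests: recovery of centre and width within 0.5% across widths 0.1–1 THz
  and centres 1–8 THz, for Lorentzian and Gaussian shapes.
- `estimate_lod_baseline()` synthesizes the baseline noise that the LOD
  definition requires: the zero-analyte spectrum is perturbed by
  multiplicative Gaussian noise on A(f) (default relative amplitude 10⁻³),
  the resonance is re-extracted `n_reps` times (default 25), and σ_b is the
  sample standard deviation of the extracted frequencies. A single integer
  seed makes the whole pipeline bit-reproducible.

What these emulate is instrument noise on an otherwise ideal spectrum. What
they do not emulate: correlated baseline drift, water-vapour absorption
lines, fabrication disorder in the graphene (finite minimum carrier
density), analyte polydispersity, or adsorption kinetics. Passing tests
therefore certify the computational chain, not agreement with any
laboratory measurement. In the small-noise regime the extracted σ_b grows
approximately linearly with the noise amplitude; at larger amplitudes the
discrete argmax wanders across the noise-flattened peak top and σ_b grows
sub-linearly — the test suite pins the linear regime (amplitudes
2–8×10⁻⁵ on a 1200-point grid).

## Problem sizes

The shipped defaults keep every stage at interactive scale: PNP grids of
48–512 cells (the convergence study uses 64/128/256), frequency grids of
600–2000 points, concentration sweeps over the four study values, and
25–100 noise replicates for σ_b. The full test suite and the acceptance
script each run in well under a minute of single-core time at these sizes,
and all of them scale linearly if finer resolution is wanted.

## Known limitations

- The gating chain treats the adsorption isotherm parameters as given;
  nothing calibrates them to measured binding data.
- The Gouy–Chapman capacitance is evaluated at the configured diffuse-layer
  potential (default 0); the capacitance ladder is not iterated to joint
  self-consistency with the gating potential, matching the constant-C
  spirit of the gating relation.
- Optics are normal-incidence and unpatterned: no angular interrogation, no
  ribbon/disk plasmon dispersion, no magneto-optics.
- The PNP solver is strictly 1-D and point-ion (no steric corrections, no
  electroosmosis); protein structure enters only through z, D and size.
- Absolute agreement with any specific fabricated device is out of scope:
  the absorber geometry here is a parametrized stand-in for a device whose
  full dimensions are not published, and the package's claims are the
  relative/structural ones its tests verify (limits, identities,
  monotonicities, mode ordering).
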