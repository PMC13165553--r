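# grapheneSPR

Computational model of an electrolyte-gated graphene perfect-absorber
surface-plasmonic-resonance (SPR) biosensor for the renal/hematological
biomarker β2-microglobulin (β2M, ~11.8 kDa, net charge −2 at neutral pH).
The package is aimed at device modellers and biosensor researchers who want
a desk-scale, fully scriptable version of this class of device: no FEM
license, every physical knob exposed, every step testable against closed
forms.

## The model

The sensing chain couples four pieces of physics:

1. **Double-layer electrostatics.** The graphene–electrolyte interface is a
   Stern capacitor — Helmholtz layer `C_H = ε0 εH/dH` in series with the
   diffuse Gouy–Chapman layer `C_GC = (εr ε0/λD) cosh(zeφ/2kBT)` — giving
   `C_EDL`. Graphene's finite density of states adds its quantum capacitance
   `C_Q = (2e²kBT/π(ħvf)²) ln[2(1+cosh(eV_ch/kBT))]` in series:
   `1/C_total = 1/C_EDL + 1/C_Q`.
2. **Electrolyte gating.** Adsorbed β2M (Langmuir isotherm by default)
   shifts the graphene sheet density `n`; the gating energy
   `E_g = ħ vf √(πn)/e + n e/C` (with `C = C_EDL` or `C_total`) sets the
   operating Fermi level of the graphene. Because `C_total < C_EDL`,
   including the quantum capacitance *amplifies* the gating response — the
   device's central design claim.
3. **Transport in the diffuse layer.** A finite-volume
   Poisson–Nernst–Planck solver (Scharfetter–Gummel fluxes, planar or
   spherical 1-D domains, charge-free Stern slab as a series dielectric)
   resolves the potential and concentration profiles of the charged protein
   and background ions; its linear regime reproduces the Debye–Hückel
   `φ0 exp(−x/λD)` screening profile.
4. **Absorber optics.** Graphene sheet conductivity from the Kubo/RPA
   intraband + interband forms, cascaded through an exact 2×2
   transfer-matrix model of the stack electrolyte / graphene / dielectric
   spacer / graphene / PEC at normal incidence. With a perfect-electric-
   conductor backing, `A(ω) = 1 − R(ω)`; the absorption resonance
   blueshifts as the Fermi level rises.

From the spectra at the configured analyte concentrations the package
extracts the resonance (`f_r`, FWHM by parabolic/linear interpolation) and
the six standard figures of merit: sensitivity `S = Δf/Δc`,
`FOM = S/FWHM`, `Q = f_r/FWHM`, `SNR = Δf/FWHM`, `DA = 1/FWHM`, and
`LOD = 3σb/S` with a seeded synthetic baseline noise model for `σb`.

## Worked example

```r
library(grapheneSPR)
el <- electrolyte_spec(c_salt = 1)          # 1 mM aqueous electrolyte, 300 K
caps <- capacitance_set(el, phi = 0, n = density_for_fermi_energy(0.3))
print(caps)
#> Capacitances (uF/cm^2): C_H=10.63 C_GC=7.203 C_EDL=4.293 C_Q=7.063 C_total=2.67
#> Debye length: 9.65 nm
```

At the 0.3 eV operating point the quantum capacitance (7.06 µF/cm²) is
comparable to the double-layer capacitance (4.29 µF/cm²), so the series
combination (2.67 µF/cm²) — and with it the charge–potential relationship —
is visibly modified: this is why the quantum-capacitance mode responds more
strongly.

```r
sw <- run_sweep(default_config(), mode = "stern_plus_qc")
print(sw)
#> Concentration sweep (stern_plus_qc mode), 4 concentrations [0.00118..1.18 g/L]
#>   f_r (THz): 3.6376 3.6808 3.8718 4.0247
#>   Pairwise metrics:
#>       c0     c1      S     FOM      Q      SNR     DA LOD delta_f   f_r  FWHM
#>  0.00118 0.0118 4.0644 0.78828 0.7139 0.008372 0.1939   0 0.04316 3.681 5.156
#>  0.01180 0.1180 1.7990 0.34394 0.7402 0.036526 0.1912   0 0.19105 3.872 5.231
#>  0.11800 1.1800 0.1439 0.02722 0.7611 0.028906 0.1891   0 0.15285 4.025 5.288
```

The resonance moves from 3.64 to 4.02 THz across the four clinically
motivated concentrations (0.00118–1.18 g/L); the sensitivity per pair falls
by a factor ~30 from the lowest to the highest pair as the Langmuir
isotherm saturates. Running the same sweep with `mode = "stern"` gives
strictly smaller shifts for every pair.

A command-line front end with subcommands `edl`, `pnp`, `spectrum`,
`sweep` and `fixtures` is provided:

```sh
Rscript inst/scripts/grapheneSPR sweep --config my.yaml --outdir out --seed 1
```

Configuration is a YAML file (any subset of keys; units like
`c_bulk: "1.18 g/L"` or `d_H: "0.5 nm"` are parsed); outputs are
unit-annotated CSVs, metrics JSON, and a manifest with per-file checksums
that reproduce exactly under a fixed seed.

## Layout

- `R/electro_dl.R` — closed-form double-layer/quantum-capacitance ladder and
  the gating relation (+ inversion).
- `R/pnp.R` — finite-volume Poisson–Nernst–Planck solver.
- `R/optics.R` — Kubo conductivity and transfer-matrix stack response.
- `R/metrics.R` — resonance features, performance metrics, concentration
  sweep, LOD baseline synthesis.
- `R/config.R`, `R/cli.R` — YAML configuration, serialization, CLI.
- `vignettes/absorber-model.Rmd` — the methods vignette: model assumptions,
  parameter choices, numerical design, limitations.
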