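Package: grapheneSPR
Title: Electrolyte-Gated Graphene Perfect-Absorber SPR Biosensor Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational model of an electrolyte-gated graphene perfect-absorber
    surface-plasmonic-resonance biosensor for beta-2-microglobulin. Implements
    Stern/Gouy-Chapman double-layer electrostatics with graphene quantum
    capacitance, a 1-D finite-volume Poisson-Nernst-Planck solver for the charged
    protein in the diffuse layer, Kubo intraband/interband graphene surface
    conductivity with transfer-matrix optics of a PEC-backed absorber stack, and
    concentration-dependent sensor performance metrics (sensitivity, figure of
    merit, quality factor, SNR, detection accuracy, limit of detection).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
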