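Package: symbiofilm
Title: Continuum Simulation of a Symbiotic Dual-Species Biofilm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates the growth of a two-species bacterial biofilm
    (a Streptococcus-Veillonella type oral community) as a continuum
    free-boundary problem. Biomass volume fractions are advected by a
    potential growth flow whose divergence equals the net volumetric
    biomass production; growth follows Monod kinetics on a diffusing
    nutrient (saliva) coupled through a lactic-acid intermediate that is
    produced by the Streptococcus, consumed by the Veillonella, and
    inhibits the Streptococcus. Provides finite-volume solvers on a
    structured grid, mixed/random-field/patch initial conditions, a
    competitive-model ablation, homogenization metrics, and a scriptable
    command-line interface with CSV/VTK/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
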