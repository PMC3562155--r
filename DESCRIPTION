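Package: ptsflux
Title: Phosphoryl Flux Analysis of the Two-Branch Phosphotransferase System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a mass-action phosphorelay model of the two
    phosphotransferase system (PTS) branches of Pseudomonas putida (the
    fructose C branch and the regulatory Ntr branch, linked by phosphoryl
    cross talk) with constraint-based estimation of equilibrium constants
    and PEP/pyruvate ratios from strain-by-condition PtsN phosphorylation
    data. Includes a small-scale flux balance analysis engine with
    growth-constrained uptake minimization, non-growth-associated
    maintenance calibration, a virtual-carbon casamino-acid feed, and flux
    variability analysis; metabolic control analysis utilities (structural
    rank, concentration control coefficients); a two-point power-law
    characterization of the PEP/pyruvate node; and a synthetic-data
    generator so the full pipeline is testable without wet-lab
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
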