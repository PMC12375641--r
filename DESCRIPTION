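Package: radbioeval
Title: Radiobiological Evaluation of Radiotherapy Dose Distributions
Version: 0.1.0
Authors@R:
    person("Plan", "Evaluation Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dosimetric and radiobiological evaluation of external
    beam radiotherapy dose distributions. Computes differential and cumulative
    dose-volume histograms (DVH) from 3D dose grids with binary structure
    masks, the standard plan-quality metrics (Dx%/Vx, conformity index,
    gradient measure, ICRU homogeneity), equivalent uniform dose (EUD),
    Poisson tumor control probability (TCP) and Lyman-Kutcher-Burman normal
    tissue complication probability (NTCP) under a built-in thoracic model
    registry, and the Friedman rank-sum / Dunnett many-to-one statistical
    comparison of paired calculation conditions. A synthetic thorax phantom
    cohort generator emulates paired dose-engine and contrast-agent
    perturbations for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
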