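Package: pelletShell
Title: Peripheral Expression-Shell Analysis of Fungal Micro-Colonies from
    Large-Particle Flow Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Whole-population analysis of Aspergillus niger micro-colony
    (pellet) size and secretion-gene reporter fluorescence measured on a
    large-particle flow cytometer. Converts time-of-flight to diameter with a
    quadratic bead calibration, applies the instrument gating rules, and
    summarises size distributions (percentile categories, bootstrap mode with
    confidence interval, Kolmogorov-Smirnov, chi-square and Kruskal-Wallis
    comparisons). Fits hyperbolic fluorescence-per-volume and
    fluorescence-per-surface models by nonlinear median (quantile) regression
    and inverts spherical-shell geometry to infer the width, relative radius
    and volume fraction of the peripheral zone in which secreted-protein genes
    are expressed. A seeded synthetic-population generator provides ground
    truth for every stage, and a direct geometric-inversion oracle validates
    the shell estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
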