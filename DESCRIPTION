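Package: retinaquant
Title: Quantitative Retinal Birefringence, Microvascular Fractal Density
    and Blood-Flow Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of retinal imaging endpoints in
    myopia research. Computes phase retardation per unit depth (PR/UD) of the
    peripapillary retinal nerve fiber layer from circumpapillary
    polarization-sensitive OCT scans; transforms enface OCT-angiography
    angiograms into annulus-restricted skeletonized microvessel maps and
    measures their box-counting fractal dimension with Bennett ocular
    magnification correction; summarizes retinal function imager blood-flow
    velocity tables; and runs the cohort statistical layer (one-way ANOVA with
    Fisher LSD post hoc tests, Pearson correlation, multiple regression, and
    noncentral-F sample-size solving). A synthetic-data generator emulates
    three-group (healthy control, moderate and high myopia) study cohorts,
    circumpapillary scans with known retardation slopes, vessel networks with
    known calibers, and fractal fixtures with closed-form dimension, so every
    stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
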