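Package: shelfkin
Title: Degradation Kinetics and Arrhenius Shelf-Life Modelling for Stored Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temperature-accelerated storage studies of perishable
    foods: per-temperature zero- and first-order degradation-kinetics fitting
    of quality indices (TBARS, TVB-N, pH, texture, sensory score), Arrhenius
    estimation of activation energy and pre-exponential factor, threshold-based
    shelf-life prediction and predicted-versus-actual validation. Supporting
    analytics include TBARS assay arithmetic from a linear standard curve,
    total volatile basic nitrogen freshness classification, fatty-acid
    shorthand-code parsing with SFA/MUFA/PUFA class aggregation and nutrition
    indices, two-block NIPALS partial least squares regression with
    correlation loadings, Pearson correlation tables with significance flags,
    and a seeded synthetic-data generator with known kinetic ground truth for
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
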