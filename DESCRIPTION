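Package: gliaEngulf
Title: Quantification of Glial Engulfment of Synapses in 3D Fluorescence Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Object-based quantification of synaptic material inside glial
    cells from multi-channel 3D confocal-style image stacks: per-channel
    adaptive local-mean thresholding, 3D connected-component extraction,
    object-overlap colocalization with a configurable minimum-overlap rule,
    burden and normalization metrics, and amyloid-plaque proximity
    stratification. Also analyses live-imaging phagocytosis assays
    (phagocytosis indices, within-experiment control normalization, area
    under the curve, post-wash degradation metrics) and provides the
    matching group-comparison statistics (Tukey ladder-of-powers
    transformation, random-intercept mixed models with Tukey-corrected
    contrasts, fold changes, correlations). A synthetic-data module
    generates image stacks with planted ground truth and phagocytosis
    time courses so the full pipeline is testable end to end without
    real tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    xml2,
    lme4,
    lmerTest,
    emmeans,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
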