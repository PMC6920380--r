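Package: neuroquant
Title: Quantitative Pipeline for Focused-Ultrasound Enhanced Intranasal
    Neurotrophin Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative readouts of focused-ultrasound
    blood-brain-barrier-opening drug-delivery studies in Parkinsonian
    mouse models: DAB/tyrosine-hydroxylase immunohistochemistry
    quantification via optical-density colour deconvolution and
    pooled-statistics thresholding, passive cavitation detection dose
    metrics (harmonic and ultraharmonic stable cavitation dose, inertial
    cavitation dose), amphetamine-elicited rotation counting with Grubbs
    outlier screening, and the associated group statistics (paired t,
    one-way ANOVA, Holm-Sidak step-down correction). Includes forward
    simulators for brightfield histology sections, cavitation pulse
    recordings and rotation traces with known ground truth, so every
    analysis stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
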