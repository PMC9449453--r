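Package: nucmorph
Title: Biomarker-Optimized Live/Dead Neuron Classification from Morphology Images
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for training and interrogating
    biomarker-optimized convolutional classifiers of neuronal death.
    Synthetic two-channel fluorescence time-lapse fields (a green
    calcium-sensitive death indicator and a red morphology marker, either
    freely diffusing or nuclear-localized) are simulated with per-cell
    ground truth; images are background-subtracted, registered, segmented
    and tracked; cells are weakly labeled live or dead from the ratiometric
    death-indicator signal using empirical thresholds; a small residual
    convolutional network is trained on morphology crops alone; and the
    network's decision strategy is quantified with guided Grad-CAM
    attribution against ground-truth phenotype masks, alongside
    precision-recall and simulated-curator benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
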