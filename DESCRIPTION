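Package: trapcount
Title: Insect Counting for Camera-Based Smart Traps at the Edge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for camera-based electronic insect traps:
    programmatic synthesis of ground-truth labeled trap images by compositing
    insect cutouts (sprites) onto trap backgrounds, a small counting-by-regression
    convolutional network trained with mean-squared-error loss, post-training
    8-bit weight quantization for microcontroller deployment, the per-class
    counting-accuracy statistic alpha = 1 - |Mc - Ac|/Mc, and a simulated daily
    trap duty-cycle with change-triggered uploads and a battery-life estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
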