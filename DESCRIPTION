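Package: adfsnet
Title: Adaptive Domain Feature Separation for Cross-Season Hyperspectral Seed Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-domain classification of single-seed hyperspectral image
    cubes with an adaptive domain feature separation (ADFS) network. The
    feature space learned from a convolutional base extractor is split into a
    shared subspace, aligned across harvest seasons with a cosine distance
    loss, and two private subspaces carrying class-specific and
    domain-specific information; three classifier heads (class, domain, and
    joint domain-class) train the separation and only the domain-irrelevant
    features are transferred. Includes the standard comparison strategies
    (source-only CNN, DANN with a gradient reversal layer, pre-training and
    fine-tuning updates), semi-supervised transfer protocols with labeled
    target fraction sweeps, a synthetic two-season seed cube generator with
    controllable spectral drift, ENVI and RDS cube input/output, and tidy
    evaluation reports with confusion matrices, ablation over feature sets,
    and feature embedding export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
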