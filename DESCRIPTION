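Package: emorfi
Title: Distributed Information Encoding and Decoding with Self-Organized
    Colony Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes characters as braille-like cell-seeding configurations that
    grow, under a stochastic kernel-convolution colony model, into branching
    patterns, and decodes the patterns with trained convolutional neural
    networks. Includes the growth simulator (expansion/inhibition kernel,
    per-step kernel noise, plate-boundary influence, domain-shape encryption,
    center cropping), balanced dataset generation and preprocessing, a compact
    CNN decoder with stacked-generalization ensembles, majority voting and
    predictive-uncertainty metrics, a text-to-pattern-frame codec, and a 1D
    elementary cellular-automaton encoder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    jsonlite,
    png,
    EBImage,
    pROC,
    tibble,
    ggplot2,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
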