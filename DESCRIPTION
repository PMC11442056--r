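Package: embryo3d
Title: Dual-Stage Deep Learning for Blastocyst Implantation Prediction
    from Tomographic Image Stacks
Version: 0.1.0
Authors@R:
    person("Embryo3d", "Developers", email = "embryo3d@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting blastocyst implantation from 11-slice
    tomographic image stacks acquired by time-lapse incubators, combined
    with nine conventional embryo evaluation (CEE) factors. Provides a
    seeded synthetic-phantom generator with ground-truth masks, a compact
    encoder-decoder segmentation network for well-frame background
    elimination, 3D volume reconstruction with rotation augmentation, the
    nine univariate CEE regression feature transforms (fitting, evaluation
    and multicollinearity screening), a fused 3D-CNN + CEE late-fusion
    classifier trained under nested fivefold cross-validation, and a
    statistical evaluation harness (ROC/AUC with DeLong variance and
    paired test, Youden cut-off, confusion statistics, Mann-Whitney U,
    two-way ANOVA, SART age-band subgroup AUC). Neural networks are
    implemented natively (RcppArmadillo convolution kernels, R training
    loop) so the whole pipeline runs on one CPU without external
    deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
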