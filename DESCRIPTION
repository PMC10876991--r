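Package: pseudovar
Title: Semi-Supervised Convolutional Prioritization of Regulatory Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes noncoding regulatory variants from per-variant
    annotation feature matrices with a small one-dimensional convolutional
    network trained by semi-supervised self-training. A supervised model is
    fit on labeled variants under k-fold cross-validation, out-of-fold
    probabilities for an unlabeled variant pool are filtered by a per-variant
    one-sample t-test against the decision boundary and by symmetric
    upper/lower probability thresholds, and the model is retrained on the
    pseudo-label-augmented set. Includes dataset construction from VCF and
    eQTL-style association tables (positive intersection, P-value and allele
    frequency negative filters, curated-negative windows), mutual-information
    and random-forest feature ranking, ROC/PR evaluation metrics, and a
    synthetic-data generator with planted class signal for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    ranger,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
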