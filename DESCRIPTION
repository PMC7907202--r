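Package: nodulefuse
Title: Lung Nodule Malignancy Classification from CT Shape, Texture, Size
    and Exhaled-Breath Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computer-aided diagnosis pipeline for pulmonary nodules that
    combines three image-derived markers from a single CT scan with an
    exhaled-breath biomarker panel. Shape complexity is quantified by
    spherical-harmonic reconstruction errors over an Attraction-Repulsion
    spherical parameterization of the nodule surface; appearance by the
    Gibbs-energy histogram of a contrast/offset-invariant 7th-order
    Markov-Gibbs random field; size by the equivalent sphere diameter fed
    to a k-nearest-neighbour classifier; and breath by 27 carbonyl
    volatile-organic-compound concentrations. The four marker groups are
    fused by stacked-autoencoder plus softmax classifiers with
    leave-one-subject-out and split evaluation. Includes a synthetic
    cohort generator so the full pipeline is testable without clinical
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    pROC,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
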