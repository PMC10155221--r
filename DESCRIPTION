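Package: stldecode
Title: Self-Taught Learning for Decoding fMRI Statistic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for self-taught learning on 3D fMRI statistic
    maps: curation of repository-style metadata manifests, resampling and
    normalisation of NIfTI volumes onto a common 4 mm analysis grid,
    subject-wise nested cross-validation plans, 3D convolutional
    autoencoders pretrained on unlabelled map corpora, transfer of encoder
    weights into convolutional classifiers (including partial transfer and
    layer freezing), evaluation with macro-averaged metrics and paired
    one-tailed t-tests, and between-subject feature-map correlation
    analyses. A synthetic statistic-map generator emulates the
    class/subject/study structure of public repositories so the whole
    pipeline can be exercised without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
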