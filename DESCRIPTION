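Package: urinmr
Title: Urinary 1H-NMR Metabolomics: Cohort Simulation, Spectral
    Preprocessing, Random-Forest Dissimilarity and PLS-LDA with Repeated
    Double Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for untargeted urinary 1H-NMR metabolomics of
    two-group (e.g., exposed/control) cohorts. Simulates urine-like
    spectra with a configurable metabolite panel and known ground truth;
    preprocesses spectra (apodization and Fourier transform, asymmetric
    least-squares baseline correction, segment-wise correlation
    alignment, adaptive intelligent binning, probabilistic quotient
    normalization, log transform and auto-scaling); embeds samples by
    unsupervised random-forest dissimilarity and principal coordinates
    analysis with a permutation-based confounder screen; and fits
    PLS-LDA discriminant models validated by repeated double
    cross-validation with permutation tests and sign-stable selection of
    discriminant variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
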