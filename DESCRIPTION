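Package: ramanpcad
Title: Chemometric PLS-DA Pipeline for Raman Spectra of Dried Biofluid Droplets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable chemometric workflow for classifying preclinical
    Alzheimer's disease from Raman spectra of dried cerebrospinal-fluid droplets:
    Savitzky-Golay smoothing, asymmetric-least-squares (Whittaker) baseline
    correction and standard-normal-variate scaling; NIPALS PLS-DA with
    random-subset cross-validation; iterative backward variable elimination
    driven by VIP and selectivity-ratio scores; jackknife stability selection
    with frequency thresholding; and permutation testing. A synthetic-spectrum
    generator with planted class-discriminative bands and cohort batch effects
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
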