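Package: ramansalt
Title: Raman Spectral Preprocessing and Gaussian Process Quantification of Plant Salt Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for quantifying salinity stress in plant
    leaves from Raman spectra. Implements piecewise-linear fluorescence
    baseline correction anchored at local minima, boxcar denoising, L2
    (vector) normalization and quantile-based outlier elimination;
    second-derivative sub-peak counting and multi-Gaussian band
    deconvolution of the Amide I region; and exact Gaussian process
    regression with a rational quadratic kernel (plus squared-exponential,
    Matern-5/2 and exponential alternatives, ridge and regression-tree
    baselines) mapping preprocessed spectra to medium NaCl concentration in
    mM. A synthetic spectrum generator with concentration- and
    week-dependent band structure makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    minpack.lm,
    rpart,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
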