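Package: nirsense
Title: Calibration of Sensory Attributes from Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline that calibrates trained-panel sensory
    scores of dry-cured meat against Fourier-transform near-infrared (NIR)
    spectra. Provides spectral pre-treatments (cubic smoothing spline,
    multiplicative scatter correction, standard normal variate, finite
    difference derivatives), column normalizations, Kennard-Stone and SPXY
    calibration/prediction partitioning, epsilon- and nu-support-vector
    regression with hyperparameters tuned by a hybrid particle swarm plus
    pattern search minimizing 5-fold cross-validated RMSE, a NIPALS partial
    least squares baseline, and figures of merit (RMSE, R-squared, relative
    standard deviation, elliptical joint confidence region of the
    observed-versus-predicted line, Durbin-Watson residual test). A synthetic
    data generator emulates the instrument geometry and sensory score
    structure of a 40-sample dry-cured loin study so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
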