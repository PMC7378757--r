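Package: fallsense
Title: Fall and Activity-of-Daily-Living Detection from Chest-Worn Triaxial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, segmentation, feature extraction and evaluation
    pipeline for detecting falls and activities of daily living (ADL) from
    chest-worn triaxial accelerometer recordings sampled at 50 Hz. Generates
    annotated synthetic recordings that follow a 35-subject study design
    (6 ADL events and 9 fall events per subject separated by 5-6 s rests),
    extracts 2 s peak-centred event segments (101 samples per axis), computes
    a 72-value spatial and frequency-domain feature vector per event
    (moment statistics, autocorrelation peaks, Welch power-spectral-density
    peaks and band powers), and evaluates kNN, linear and RBF support vector
    machines (with one-vs-one error-correcting output codes for multiclass),
    linear discriminant analysis and CART decision trees under
    leave-one-subject-out cross-validation, including decision-tree-importance
    feature selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    yaml
Suggests:
    withr,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
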