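Package: gaitstager
Title: Severity Staging of Parkinsonian Gait from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stage the severity of Parkinsonian gait from 2-D
    pose-keypoint trajectories. From ankle, heel and hip landmark tracks the
    package builds two gait signals (signed inter-ankle separation and per-foot
    height), denoises them by Fourier truncation, detects gait-cycle extrema,
    and derives six spatiotemporal features (step length, step time, stride
    time, stride length, swing time, double support). Severity-graded training
    data are synthesized by linear interpolation between a normal and a
    Parkinsonian exemplar gait and labeled with four Hoehn & Yahr-derived
    stages. K-nearest-neighbour, support-vector-machine and gradient-boosting
    classifiers are tuned by grid search under stratified cross-validation,
    screened with learning-curve fit diagnostics, and evaluated with
    one-vs-rest confusion metrics, ROC/AUC and permutation feature importance.
    A parametric gait simulator provides reproducible exemplar recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
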