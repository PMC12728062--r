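Package: rehabloop
Title: Closed-Loop Assistance-as-Needed Simulation for Multimodal Hand Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis stack for sensor-driven, assistance-as-needed
    (AAN) hand rehabilitation. Generates synthetic virtual-patient data (surface
    EMG, inertial measurement unit streams, Fitts-style trial logs, longitudinal
    training courses), preprocesses multimodal signals (Butterworth and notch
    filtering, extended Kalman filter orientation fusion, Hampel cleaning,
    Teager-Kaiser onset detection, windowing), extracts kinematic, EMG,
    cross-modal and task-level features (SPARC, log dimensionless jerk,
    co-contraction index, Fitts throughput, mutual information), trains a stacked
    random forest + support vector regression model with a ridge meta-learner and
    sigmoid composite score, and closes the loop with a dual-channel AAN
    controller (assistance and task difficulty) with dead zone, rate limiting,
    hysteresis and safety overrides. Includes proxy-label construction,
    grouped cross-validation harnesses, and the clinical statistics toolbox
    (paired t with Hedges-corrected effect size, ICC(2,1), weighted kappa,
    Bonferroni correction, outcome-table arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
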