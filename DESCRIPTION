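Package: glovekin
Title: Finger-Opposition Kinematics, Reliability and Impairment Scoring from Sensor-Glove Event Streams
Version: 0.1.0
Authors@R: person("glovekin", "maintainers", email = "glovekin@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of repetitive thumb-to-finger
    opposition tasks recorded with sensor-engineered gloves. Reads and validates
    touch-event streams and cohort metadata; extracts per-trial kinematic
    parameters (touch duration, inter-tapping interval, movement rate,
    inter-hand interval); quantifies test-retest reliability (two-way
    random-effects absolute-agreement ICC, standard error of measurement,
    smallest real difference); compares patient and control groups
    (Mann-Whitney, age-adjusted partial rank correlations with clinical scales,
    disability-strata trend tests); and builds a composite finger motor
    impairment score by age-adjusted stepwise logistic regression with ROC and
    leave-one-out cross-validated discrimination. Includes a calibrated
    synthetic cohort generator (Gaussian-copula clinical covariates, simulated
    paced and self-paced 60-s trials) so the full pipeline is testable without
    patient data, and a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
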