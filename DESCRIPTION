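Package: mcrefer
Title: Monte Carlo Dropout Uncertainty and Decision Referral for Disease
    Screening Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Approximate Bayesian uncertainty for feed-forward softmax
    classifiers via Monte Carlo dropout, together with an
    uncertainty-informed decision-referral evaluation framework for
    medical screening tasks. Provides small trainable dropout networks,
    exact dropout-mask enumeration oracles, predictive posterior
    summaries (predictive mean, predictive standard deviation, binary
    entropy), risk-coverage referral curves with percentile-bootstrap
    confidence intervals and random-referral baselines, ROC/AUC and
    operating-point metrics, disease-level composition and
    contra-lateral ambiguity analyses on simulated ordinal graded
    cohorts, and autoencoder reconstruction-error anomaly scoring of
    feature vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
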