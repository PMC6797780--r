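Package: metawager
Title: Time-Wagering Confidence, Metacognition and Reversal-Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-alternative perceptual decision tasks in
    which post-decision waiting time ("time wagering") serves as a trial-by-trial
    confidence report. Provides a validated long-format trial-table model with the
    standard trial filters (reaction-time outlier removal, wager-trial selection),
    type-1 signal detection estimates (d-prime, criterion) and type-2 metacognitive
    sensitivity (meta-d-prime and efficiency meta-d'/d') fitted by maximum
    likelihood from waiting times binned into confidence ratings, Win-Stay /
    Lose-Switch strategy scoring with a rule-based repetition index for reversal
    learning, exponential learning-curve fitting with bootstrap confidence
    intervals, permutation tests with Bonferroni correction, and a task simulator
    (signal-detection observer, wagering policy, probabilistic delayed reward,
    two-state reversal learner, regional-inhibition parameter shifts) that
    generates data with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
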