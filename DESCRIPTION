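Package: trinetdyn
Title: Dynamic Triple-Network Interaction Analysis for Resting-State Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying dynamic time-varying interactions among the
    salience (SN), frontoparietal (FPN, split left/right), and default mode
    (DMN) brain networks from component time series. Implements exponentially
    tapered sliding-window correlations, group-wise k-means consensus
    clustering into latent brain states with cluster-validity majority voting,
    dwell-time statistics, the SN-centred Network Interaction Index (NII) with
    per-state and per-subject summaries, group inference (paired and Welch
    t-tests, Bonferroni correction, brain-behavior correlations, treatment
    response regression), CART classification under leave-one-out
    cross-validation with a no-information-rate test, and a hidden-Markov
    synthetic cohort generator with linked behavioral scores for ground-truth
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
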