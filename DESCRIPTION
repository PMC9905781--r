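Package: hypnoagree
Title: Multi-Scorer Sleep Staging Ambiguity, Hypnodensity, and Auto-Scorer Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sleep staging ambiguity from multi-scorer
    polysomnography stagings. Builds hypnodensity matrices (per-epoch sleep
    stage probabilities) from panels of manual scorers or from a
    probability-emitting auto-scorer, measures the combinatorial decay of
    complete inter-scorer agreement with increasing panel size and fits the
    power model y = a*x^b to it, constructs unbiased majority-vote consensus
    stagings with reliability-weighted tie-breaking, evaluates scorers and
    auto-scoring with Cohen's kappa against three comparator schemes and with
    ICC(2,1) absolute-agreement reliability of probability series, and derives
    standard sleep report parameters (stage times, sleep/REM latency, sleep
    efficiency) directly from stage probabilities. Includes a configurable
    multi-scorer simulator (latent Markov architecture, Dirichlet epoch
    ambiguity, per-scorer confusion bias, noisy auto-scorer) so every analysis
    can be exercised end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2
Config/testthat/edition: 3
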