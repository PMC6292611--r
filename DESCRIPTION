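Package: cesize
Title: Sample-Size Optimisation for Binary Composite Endpoints
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Design tools for two-arm randomised trials that use a binary
    composite endpoint. Given a panel of candidate binary outcomes (control-arm
    event rates, treatment effects as risk ratios, and pairwise association
    assumptions expressed either as exact joint probabilities or as nine
    qualitative scenarios anchored to the Frechet bounds), 'cesize' computes
    per-group sample-size requirements for any combination of outcomes, selects
    the combination that minimises the sample size by greedy forward selection,
    quantifies the gap to the exhaustive optimum, and runs nine-scenario
    association sensitivity analyses. Includes Monte-Carlo validation of
    composite event rates and power, a reproducible random panel generator,
    JSON/CSV study configurations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
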