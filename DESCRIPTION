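Package: causalpaths
Title: Causal Discovery and Effect Estimation for Longitudinal Clinical
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Data-driven causal analysis of baseline and follow-up clinical
    measures. Learns a partial ancestral graph (PAG) from a subject-by-variable
    table with a two-stage hybrid search (greedy equivalence search with a
    penalised Gaussian likelihood score, followed by constraint-based
    refinement with Fisher-Z conditional-independence tests that re-admits
    latent confounders) under temporal background knowledge; estimates raw and
    standardised causal effect sizes by fitting a linear structural equation
    model to the PAG; quantifies graph stability by jackknife and bootstrap
    edge concordance; and reports causal pathways and cross-timepoint causal
    cycles. Includes a linear-Gaussian simulator for benchmark systems and for
    the published functional-outcome model of first-episode schizophrenia.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
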