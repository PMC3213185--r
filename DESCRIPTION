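Package: boolsig
Title: Asynchronous Boolean Dynamics and Structural Analysis of Signaling
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for logical (Boolean) models of signal transduction
    networks: a rule dialect parser with exact simplification and
    disjunctive-normal-form canonicalization, two-step network reduction
    (logical steady state analysis and mediator elimination), general
    asynchronous state-transition-graph construction with attractor,
    basin-of-attraction and Markov-chain absorption analysis, expanded-network
    structural analysis (complementary and composite vertices, cascading
    deletion, simple-path importance values), systematic in-silico
    knockout/over-expression screening, and a random Boolean network
    generator. Ships the T cell large granular lymphocyte (T-LGL) leukemia
    survival signaling network and its reduced sub-networks as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
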