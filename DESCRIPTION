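Package: actualcause
Title: Quantitative Actual Causation in Discrete Dynamical Causal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Answers "what caused what?" for a single state transition of a
    discrete dynamical causal network (Boolean or multi-valued logic networks,
    simple neural circuits, gene-regulatory toy models). Computes cause and
    effect repertoires under do-interventions with uniform causal
    marginalization, quantifies the strength of causal links in bits via
    minimum-information partitions (integrated cause/effect information),
    applies the exclusion and minimality principles to identify actual causes
    and effects of every sub-occurrence, and assembles the complete causal
    account of the transition together with its account-level irreducibility.
    Includes closed-form oracles for linear threshold units and
    disjunction-of-conjunction gates, a registry of worked example networks,
    JSON import/export of networks and accounts, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
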