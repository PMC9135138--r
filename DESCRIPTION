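Package: garmine
Title: Generalized Association Rule Mining on Categorical Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines generalized association rules, whose left-hand side is a
    conjunction of disjunctions of elementary equalities (AND of OR-clauses),
    from categorical data tables with single-character cells and missing
    values. Rule candidates are generated by filling a user-supplied rule
    pattern with elementary equalities, pruned with a sound branch-and-bound
    support bound, filtered on support, confidence, lift and leverage,
    greedily simplified under a relative lift tolerance, and reported as
    tibbles, plain-text and XML. Includes a seeded synthetic-table generator
    that plants rules with exactly realized metrics for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
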