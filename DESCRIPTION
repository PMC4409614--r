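Package: agonet
Title: Agonistic Interaction Networks in Group-Housed Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, weighted social networks of agonistic
    interactions (fights) from behavioral event logs of group-housed pigs,
    computes binary and weighted centrality measures (degree, in-/out-degree,
    betweenness, ingoing/outgoing/undirected closeness) from scratch on the
    per-pen fight networks, and compares the measures across successive age
    levels (weaned pigs, growing pigs, gilts) with Kruskal-Wallis tests,
    significance letters, and Spearman rank correlations within and between
    age levels. Includes a synthetic study generator that emulates the
    structure of post-mixing fight data so the full pipeline is testable
    without observational recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    tools,
    utils,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
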