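Package: rcanet
Title: Reverse Causal Analysis of Omics State Changes on Signed Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates every node of a signed causal knowledge graph as a
    mechanistic hypothesis for observed omics state changes. Replicate
    expression matrices and phosphoprotein treated/vehicle ratio tables are
    quantified into signed increase/decrease/no-change calls; each candidate
    upstream regulator is scored by a hypergeometric Richness p-value
    (over-representation of observed changes among its predictions) and a
    binomial Concordance p-value (directional agreement of unambiguous
    predictions); significant hypotheses shared across experiments are merged
    into a Causal Network Model with per-experiment explanatory coverage.
    Includes a planted-perturbation synthetic benchmark generator for
    knowledge graphs and expression/phosphoproteomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
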