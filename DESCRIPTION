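Package: cehn
Title: Cascading Hazard Network Analysis of Escalator Accident Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed weighted cascading-hazard networks from coded
    accident hazard chains (L-space representation: consecutive hazards in a
    chain are joined by a directed edge, repeats accumulate as integer
    weights). Computes degree and strength, un-weighted and max-normalized
    weighted clustering coefficients, and exact shortest-path node and edge
    betweenness; classifies hazards as trigger, transitional or consequence
    from in/out-strength asymmetry and ranks critical hazards. Includes the
    Beijing metro escalator accident fixture (61-hazard codebook and 327
    coded chains), Pajek and edge-list interchange, a seeded first-order
    Markov chain generator for synthetic corpora, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
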