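Package: beeflow
Title: Movement Influence, Trophallaxis and Sociability Analysis for Tracked Honey Bee Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing automated tracking data from barcoded honey
    bee colonies: kinematic quantification with stationarity filtering,
    merging and duration-filtering of trophallaxis (food-sharing) events into
    per-bee sociability scores, extraction of proximal-interaction windows,
    estimation of directed movement influence between bees via vector
    autoregressive models and information partial directed coherence (iPDC)
    integrated into information flow in bits, rule-based behavioural state
    classification from entrance-trip logs and laboratory assays, and
    downstream association statistics (polygenic scores, hypergeometric
    gene-list overlap, group comparisons). Includes a seeded synthetic colony
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
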