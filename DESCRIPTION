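Package: SymptomNet
Title: Weighted Signed Symptom Networks with Tuning-Parameter Centrality
    and Node Predictability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates weighted signed symptom networks from psychometric
    score tables by significance-thresholded Spearman correlation, computes
    weighted centrality measures with the Opsahl tuning parameter (blended
    degree/strength, Dijkstra shortest-path betweenness with fractional tie
    credit, closeness), quantifies node predictability by neighbour
    regression, lays networks out with a deterministic Fruchterman-Reingold
    algorithm, and compares cohorts across timepoints. Includes a
    Gaussian-copula generator of block-correlated synthetic questionnaire
    cohorts over a 17-item neurocognitive/affective/psychosocial battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
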