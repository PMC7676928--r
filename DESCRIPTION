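Package: herbnet
Title: Network Pharmacology Pipelines for Herbal Compound-Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology analyses of multi-compound
    herbal medicines: ADME screening of candidate compounds by oral
    bioavailability and drug-likeness, intersection of compound targets
    with disease gene sets, construction of typed compound-target,
    compound-target-pathway and protein-protein interaction networks,
    degree and betweenness centrality with median- and mean-based node
    selection rules, and hypergeometric over-representation analysis of
    pathway gene sets. Includes a synthetic-data generator that emulates
    database exports (compound tables, target maps, scored interaction
    edges, GMT gene sets) with controlled statistical structure, and an
    end-to-end pipeline driver with a machine-readable run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
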