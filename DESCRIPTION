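Package: netpharm
Title: Network Pharmacology Screening for Multi-Herb Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible network-pharmacology inference chain for
    multi-herb formulations: curation of herb-compound tables and
    compound-target mappings, intersection of predicted targets with a
    disease gene set, construction of protein-protein interaction (PPI)
    networks from confidence-scored edge lists, degree/betweenness/closeness
    centrality analysis, iterative mean-threshold screening of hub genes,
    Fisher's exact gene-set over-representation with Benjamini-Hochberg
    correction, and assembly of multipartite
    drug-herb-compound-target-pathway networks.  Seeded synthetic-data
    generators replace live database queries so that every stage of the
    pipeline is testable offline.
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
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
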