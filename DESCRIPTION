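Package: trailspan
Title: Maximum-Span Supported Trails in Metabolic and Genomic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact mining of chains of metabolic reactions catalyzed by
    products of neighboring genes. A metabolic pathway is modeled as a
    directed reaction graph and a genome as an undirected gene-neighborhood
    graph; a correspondence function links reactions to the genes encoding
    their enzymes. For every arc of the pathway graph the package finds a
    trail (arc-distinct walk) of maximum span whose reactions are supported
    by a connected gene neighborhood, using an exact line-graph algorithm
    with strongly-connected-component condensation and partial-path
    concatenation. Per-species trails are then pooled as reaction sets and
    compared across a species panel, producing conserved-pattern tables by
    reactions and by genes. Includes KGML pathway parsing, plain-text
    genome/result formats, a brute-force oracle, and reproducible random
    instance generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
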