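Package: ppialign
Title: Pairwise Local Alignment of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds protein modules conserved between the protein-protein
    interaction (PPI) networks of two species. The two weighted networks and a
    scored, possibly many-to-many orthology map are merged into a union graph;
    an alignment graph over ortholog-pair nodes is scored with a Jaccard-style
    measure over direct and length-2 path evidence, corrected for multiple
    orthologs and locally pruned; conserved modules are grown from top-scoring
    connected 4-subgraph seeds by batch expansion. Includes an evaluation
    protocol against reference complex catalogs (precision/recall/F1,
    hypergeometric enrichment, connectivity Z-scores against degree-preserving
    random networks) and a synthetic paired-network generator with planted
    conserved complexes for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
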