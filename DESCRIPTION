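Package: moanet
Title: Mechanism-of-Action Inference from Transcriptomes via Active
    Subnetworks and Pathway Crosstalk Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the mechanism of action of a compound from
    treated-versus-control transcriptome data. Differentially expressed
    genes are projected onto a protein-protein interaction network and a
    maximally connected drug-responsive subnetwork is extracted under a
    budget of K non-differentially-expressed exception nodes. Subnetwork
    genes are ranked by degree and betweenness centrality, tested for
    pathway over-representation against GMT gene-set collections, and the
    retained pathways are de-redundified and linked into a Jaccard
    gene-overlap crosstalk network, clustered by greedy modularity
    optimisation, and mapped onto canonical oncogenic signalling pathways
    and carcinogenesis process categories. Ships a seeded synthetic-data
    module (scale-free interactome with a planted differentially
    expressed module, two-group expression matrices, GMT collections with
    controlled pairwise overlaps) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
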