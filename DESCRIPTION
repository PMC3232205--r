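Package: associationsearch
Title: Semantic Association Search and Topic-Based Ranking in Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finds and ranks semantic associations (simple relationship paths)
    between typed biomedical entities -- compounds, drugs, genes, diseases,
    side effects, pathways -- in an integrated knowledge graph. A two-stage
    search first computes hop distances from every node to the query target
    with a heap-based Dijkstra pass, then enumerates all near-shortest simple
    paths by depth-first search with admissible distance pruning. Paths are
    ranked either by length or by a literature-derived score: a Bio-LDA topic
    model (an author-topic-style latent Dirichlet allocation in which each
    token is attributed to one of its document's tagged bio-terms, with
    journal stamps) is fitted by collapsed Gibbs sampling, and consecutive
    bio-terms on a path are scored by the symmetric Kullback-Leibler
    divergence of their topic distributions. Includes seed-controlled
    synthetic graph and planted-topic corpus generators and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
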