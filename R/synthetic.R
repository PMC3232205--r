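## Seed-controlled synthetic fixtures: the 26-node worked-example graph, a
## typed Erdos-Renyi graph generator emulating the structure of an
## integrated chemical-biology resource, and a planted-topic corpus
## generator that follows the Bio-LDA forward process exactly.

#' The 26-node worked-example graph
#'
#' A fixed undirected-traversal graph on nodes "1".."26" used to illustrate
#' the bidirectional search. Its construction is pinned by four frontier
#' expansions -- from node 1: \{3,4,6,7,10\} then \{2,5,8,9,11,14,18\}; from
#' node 26: \{19,21,23,24,25\} then \{15,16,18,22\} -- with node 18 the first
#' node explored from both ends, making (1,10,18,21,26) the unique shortest
#' 1-to-26 path. The edge list (no published edge list exists; this is one
#' graph consistent with the trace) is:
#' 1-3, 1-4, 1-6, 1-7, 1-10; 3-2, 4-5, 6-8, 7-9, 10-11, 10-14, 10-18;
#' 26-19, 26-21, 26-23, 26-24, 26-25; 21-18, 19-15, 23-16, 24-22;
#' 2-12, 5-13, 15-17, 22-20.
#'
#' @return An `association_graph` (undirected traversal).
#' @export
worked_example_graph <- function() {
  e <- rbind(
    c(1, 3), c(1, 4), c(1, 6), c(1, 7), c(1, 10),
    c(3, 2), c(4, 5), c(6, 8), c(7, 9), c(10, 11), c(10, 14), c(10, 18),
    c(26, 19), c(26, 21), c(26, 23), c(26, 24), c(26, 25),
    c(21, 18), c(19, 15), c(23, 16), c(24, 22),
    c(2, 12), c(5, 13), c(15, 17), c(22, 20))
  association_graph(
    data.frame(source = as.character(e[, 1]), target = as.character(e[, 2]),
               predicate = "linked_to", stringsAsFactors = FALSE),
    traversal_mode = "undirected")
}

## default predicate by endpoint category pair (order-insensitive)
category_predicate <- function(a, b) {
  pair <- paste(sort(c(a, b)), collapse = "+")
  switch(pair,
         "compound+gene" = "binds",
         "drug+gene" = "binds",
         "disease+gene" = "associated_with",
         "disease+drug" = "treats",
         "drug+side_effect" = "causes",
         "compound+side_effect" = "causes",
         "gene+pathway" = "participates_in",
         "disease+pathway" = "involved_in",
         "gene+gene" = "interacts_with",
         "compound+drug" = "similar_to",
         "related_to")
}

#' Generate a typed random entity graph
#'
#' Erdos-Renyi graph over `n_nodes` entities whose categories are assigned
#' by `category_mix`; predicates follow endpoint-category rules (e.g.
#' drug-gene edges are "binds"), mimicking the typed structure of an
#' integrated chemical-biology triple store. Pure function of its arguments
#' and `seed`.
#'
#' @param n_nodes number of nodes.
#' @param edge_prob edge probability in (0, 1].
#' @param category_mix named numeric vector of category fractions (summing
#'   to 1 over a subset of [ENTITY_CATEGORIES]).
#' @param seed integer seed.
#' @param node_ids optional character vector of `n_nodes` ids (e.g. to share
#'   the bio-term namespace with a corpus); default ids are
#'   category-prefixed.
#' @param traversal_mode passed to [association_graph()].
#' @return An `association_graph`.
#' @export
generate_graph <- function(n_nodes, edge_prob,
                           category_mix = c(drug = 0.2, gene = 0.3,
                                            disease = 0.2, compound = 0.15,
                                            side_effect = 0.1, pathway = 0.05),
                           seed = 1L, node_ids = NULL,
                           traversal_mode = c("undirected", "directed")) {
  traversal_mode <- match.arg(traversal_mode)
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop_config("edge_prob must be in [0, 1]")
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% ENTITY_CATEGORIES))
    stop_config("category_mix names must be entity categories")
  if (abs(sum(category_mix) - 1) > 1e-6)
    stop_config("category_mix fractions must sum to 1")
  if (n_nodes < 1) stop_config("n_nodes must be >= 1")

  set.seed(as.integer(seed))
  cats <- sample(names(category_mix), n_nodes, replace = TRUE,
                 prob = unname(category_mix))
  if (is.null(node_ids)) {
    node_ids <- sprintf("%s_%04d", toupper(cats), seq_len(n_nodes))
  } else if (length(node_ids) != n_nodes) {
    stop_config("node_ids must have length n_nodes")
  }
  names(cats) <- node_ids

  src <- tgt <- character(0)
  if (n_nodes > 1) {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < edge_prob
    src <- node_ids[pairs[on, 1]]
    tgt <- node_ids[pairs[on, 2]]
  }
  pred <- mapply(function(a, b) category_predicate(cats[[a]], cats[[b]]),
                 src, tgt, USE.NAMES = FALSE)
  if (length(src) == 0) pred <- character(0)
  association_graph(
    data.frame(source = src, target = tgt, predicate = as.character(pred),
               stringsAsFactors = FALSE),
    nodes = node_ids, categories = cats, traversal_mode = traversal_mode)
}

#' Generate a planted-topic corpus by the Bio-LDA forward process
#'
#' Plants `n_topics` topics with disjoint word blocks (each topic puts
#' `word_concentration` of its mass uniformly on its own block), assigns
#' each bio-term a dominant topic round-robin (`topic_concentration` of its
#' theta mass), and one journal per topic (0.9 mass). Each document draws
#' `bioterms_per_doc` bio-terms without replacement, then generates every
#' token by bio-term (uniform) -> topic (theta) -> word (phi); the
#' document's single journal stamp is drawn from psi of a topic drawn from
#' the document's first bio-term.
#'
#' @param n_topics,n_bioterms,vocab_size,n_journals planted sizes.
#' @param n_docs,doc_len corpus shape (token count = `n_docs * doc_len`).
#' @param bioterms_per_doc bio-terms tagged per document.
#' @param topic_concentration theta mass on a bio-term's dominant topic.
#' @param word_concentration phi mass on a topic's own word block.
#' @param seed integer seed; the generator is a pure function of arguments
#'   and seed.
#' @param bioterm_ids optional character vector of `n_bioterms` ids sharing
#'   a graph's node namespace.
#' @return List with `corpus` (a `biolda_corpus`) and `truth` (class
#'   `planted_truth`: `theta`, `phi`, `psi`, `topic_of_bioterm`, `seed`).
#' @export
generate_corpus <- function(n_topics = 5L, n_bioterms = 40L,
                            vocab_size = 200L, n_journals = n_topics,
                            n_docs = 400L, doc_len = 50L,
                            bioterms_per_doc = 2L,
                            topic_concentration = 0.9,
                            word_concentration = 0.95,
                            seed = 1L, bioterm_ids = NULL) {
  sizes <- c(n_topics, n_bioterms, vocab_size, n_journals, n_docs, doc_len,
             bioterms_per_doc)
  if (any(sizes < 1)) stop_config("all sizes must be >= 1")
  if (bioterms_per_doc > n_bioterms)
    stop_config("bioterms_per_doc cannot exceed n_bioterms")
  if (vocab_size < n_topics)
    stop_config("need at least one vocabulary word per topic")

  set.seed(as.integer(seed))
  T <- as.integer(n_topics); B <- as.integer(n_bioterms)
  V <- as.integer(vocab_size); J <- as.integer(n_journals)

  words <- sprintf("w%04d", seq_len(V))
  if (is.null(bioterm_ids)) bioterm_ids <- sprintf("BT%03d", seq_len(B))
  else if (length(bioterm_ids) != B)
    stop_config("bioterm_ids must have length n_bioterms")
  journals <- sprintf("J%02d", seq_len(J))

  ## planted distributions
  topic_of <- rep(seq_len(T), length.out = B)
  theta <- matrix((1 - topic_concentration) / max(T - 1, 1), B, T)
  if (T == 1) theta[] <- 1
  for (b in seq_len(B)) theta[b, topic_of[b]] <- topic_concentration
  if (T == 1) theta[, 1] <- 1

  block <- if (T == 1) list(seq_len(V))
           else split(seq_len(V), cut(seq_len(V), T, labels = FALSE))
  phi <- matrix(0, T, V)
  for (t in seq_len(T)) {
    inb <- seq_len(V) %in% block[[t]]
    phi[t, inb] <- word_concentration / sum(inb)
    if (any(!inb)) phi[t, !inb] <- (1 - word_concentration) / sum(!inb)
    else phi[t, ] <- 1 / V
  }
  psi <- matrix(0.1 / max(J - 1, 1), T, J)
  if (J == 1) psi[] <- 1
  for (t in seq_len(T)) psi[t, ((t - 1) %% J) + 1] <- if (J > 1) 0.9 else 1
  rownames(theta) <- bioterm_ids
  colnames(theta) <- rownames(phi) <- rownames(psi) <- paste0("topic", seq_len(T))
  colnames(phi) <- words
  colnames(psi) <- journals

  documents <- vector("list", n_docs)
  for (dd in seq_len(n_docs)) {
    bset <- sort(sample.int(B, bioterms_per_doc))
    xs <- bset[sample.int(bioterms_per_doc, doc_len, replace = TRUE)]
    zs <- vapply(xs, function(b)
      sample.int(T, 1, prob = theta[b, ]), integer(1))
    ws <- vapply(zs, function(t)
      sample.int(V, 1, prob = phi[t, ]), integer(1))
    z0 <- sample.int(T, 1, prob = theta[bset[1], ])
    jj <- sample.int(J, 1, prob = psi[z0, ])
    documents[[dd]] <- list(tokens = ws, bioterms = bset, journal = jj)
  }

  ## ids are zero-padded, so sorted order equals index order and the corpus
  ## indices line up with the planted matrices
  corpus <- structure(list(documents = documents, vocabulary = words,
                           bioterms = bioterm_ids, journals = journals),
                      class = "biolda_corpus")
  truth <- structure(list(theta = theta, phi = phi, psi = psi,
                          topic_of_bioterm = stats::setNames(topic_of, bioterm_ids),
                          seed = as.integer(seed)),
                     class = "planted_truth")
  list(corpus = corpus, truth = truth)
}

#' Export a generated corpus as record lines
#'
#' @param corpus a `biolda_corpus`.
#' @return data.frame suitable for [write_corpus_records()].
#' @export
corpus_to_records <- function(corpus) {
  data.frame(
    tokens = vapply(corpus$documents, function(d)
      paste(corpus$vocabulary[d$tokens], collapse = " "), character(1)),
    bioterms = vapply(corpus$documents, function(d)
      paste(corpus$bioterms[d$bioterms], collapse = ","), character(1)),
    journal = vapply(corpus$documents, function(d)
      corpus$journals[d$journal], character(1)),
    stringsAsFactors = FALSE)
}
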