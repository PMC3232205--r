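# Independent oracles used to cross-check the search and sampling code.
# These deliberately avoid the package's indexed adjacency and heap: they
# work directly off the edge table with plain queues and recursion.

# adjacency list (node id -> character vector of neighbors) built straight
# from the edge table, honoring the traversal mode
oracle_adjacency <- function(graph, direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  e <- graph$edges
  e <- e[e$source != e$target, , drop = FALSE]  # self-loops never traversed
  adj <- stats::setNames(vector("list", length(graph$node_ids)), graph$node_ids)
  add <- function(adj, from, to) {
    for (k in seq_along(from)) adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj
  }
  if (direction %in% c("out", "both")) adj <- add(adj, e$source, e$target)
  if (direction %in% c("in", "both")) adj <- add(adj, e$target, e$source)
  lapply(adj, function(v) sort(unique(v)))
}

# queue-based BFS hop distances from every node to `target`
bfs_distances_oracle <- function(graph, target) {
  dir <- if (graph$traversal_mode == "undirected") "both" else "in"
  adj <- oracle_adjacency(graph, dir)
  dist <- stats::setNames(rep(Inf, length(graph$node_ids)), graph$node_ids)
  dist[target] <- 0
  queue <- target
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

# exhaustive enumeration of all simple source->target paths up to max_len
# hops (no pruning), as tilde-joined strings
all_simple_paths_oracle <- function(graph, source, target, max_len) {
  dir <- if (graph$traversal_mode == "undirected") "both" else "out"
  adj <- oracle_adjacency(graph, dir)
  out <- character(0)
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == target) {
      out[[length(out) + 1]] <<- paste(path, collapse = "~")
      return(invisible())
    }
    if (length(path) > max_len) return(invisible())
    for (u in adj[[v]]) if (!u %in% path) recurse(c(path, u))
    invisible()
  }
  recurse(source)
  out
}

# hop lengths admitted for a query: the shortest length always, plus lengths
# strictly below (1 + beta) * L_min (same rule the package documents)
admitted_paths_oracle <- function(graph, source, target, beta, max_len) {
  paths <- all_simple_paths_oracle(graph, source, target, max_len)
  if (length(paths) == 0) return(character(0))
  lens <- lengths(strsplit(paths, "~", fixed = TRUE)) - 1L
  L_min <- min(lens)
  keep <- lens <= max_len &
    (lens == L_min | lens < (1 + beta) * L_min - 1e-9)
  sort(paths[keep])
}

paths_of <- function(assoc_set) {
  sort(vapply(assoc_set$associations, format, character(1)))
}

# exact joint posterior over per-token topic assignments for a micro corpus
# with ONE document and ONE bio-term, by Dirichlet-multinomial enumeration
micro_topic_posterior <- function(corpus, hp) {
  d <- corpus$documents[[1]]
  stopifnot(length(corpus$documents) == 1, length(d$bioterms) == 1)
  N <- length(d$tokens)
  T <- hp$n_topics
  W <- length(corpus$vocabulary)
  J <- length(corpus$journals)
  grid <- as.matrix(expand.grid(rep(list(seq_len(T)), N)))
  lp <- apply(grid, 1, function(z) {
    n_bt <- tabulate(z, T)
    n_tw <- matrix(0, T, W)
    for (i in seq_len(N)) n_tw[z[i], d$tokens[i]] <- n_tw[z[i], d$tokens[i]] + 1
    n_tj <- matrix(0, T, J)
    n_tj[, d$journal] <- tabulate(z, T)
    val <- sum(lgamma(n_bt + hp$alpha)) - lgamma(N + T * hp$alpha)
    for (t in seq_len(T)) {
      val <- val + sum(lgamma(n_tw[t, ] + hp$beta_word)) -
        lgamma(sum(n_tw[t, ]) + W * hp$beta_word)
      val <- val + sum(lgamma(n_tj[t, ] + hp$mu)) -
        lgamma(sum(n_tj[t, ]) + J * hp$mu)
    }
    val
  })
  p <- exp(lp - max(lp))
  list(grid = grid, prob = p / sum(p))
}

# greedy one-to-one best matching of rows by cosine similarity
greedy_cosine_match <- function(true_rows, est_rows) {
  cosm <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  M <- outer(seq_len(nrow(true_rows)), seq_len(nrow(est_rows)),
             Vectorize(function(i, j) cosm(true_rows[i, ], est_rows[j, ])))
  picked <- numeric(0)
  while (any(is.finite(M))) {
    ij <- which(M == max(M), arr.ind = TRUE)[1, ]
    picked <- c(picked, M[ij[1], ij[2]])
    M[ij[1], ] <- -Inf
    M[, ij[2]] <- -Inf
  }
  picked
}

# counts re-derived from raw (z, x) assignments, for consistency checks
rederive_counts <- function(state, corpus, n_topics) {
  B <- length(corpus$bioterms); W <- length(corpus$vocabulary)
  J <- length(corpus$journals); T <- n_topics
  n_bt <- matrix(0L, B, T); n_tw <- matrix(0L, T, W); n_tj <- matrix(0L, T, J)
  jt <- state$journal_of_doc[state$doc_of]
  for (i in seq_along(state$z)) {
    n_bt[state$x[i], state$z[i]] <- n_bt[state$x[i], state$z[i]] + 1L
    n_tw[state$z[i], state$word_of[i]] <- n_tw[state$z[i], state$word_of[i]] + 1L
    n_tj[state$z[i], jt[i]] <- n_tj[state$z[i], jt[i]] + 1L
  }
  list(n_bt = n_bt, n_tw = n_tw, n_tj = n_tj)
}

# tiny literal graph from inline TSV text
graph_from_lines <- function(..., mode = "undirected") {
  load_triples(c(...), format = "tsv", traversal_mode = mode)
}
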