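## Two-stage association search: all-to-target hop distances via a heap-based
## Dijkstra pass, then depth-first enumeration of near-shortest simple paths
## pruned by the admissible condition d(s) + 1 + d'(u) within the length bound.

#' Search configuration for near-shortest association enumeration
#'
#' @param beta_slack non-negative slack: paths of length below
#'   `(1 + beta_slack) * L_min` are admitted (the shortest length itself is
#'   always admitted, so `beta_slack = 0` returns exactly the shortest paths).
#' @param max_length hard cap on hop length (>= 1).
#' @param traversal_mode optional override of the graph's traversal mode.
#' @return An object of class `search_config`.
#' @export
search_config <- function(beta_slack = 0.5, max_length = 6L,
                          traversal_mode = NULL) {
  if (!is.numeric(beta_slack) || length(beta_slack) != 1 || beta_slack < 0)
    stop_config("beta_slack must be a single non-negative number")
  if (!is.numeric(max_length) || length(max_length) != 1 || max_length < 1)
    stop_config("max_length must be a positive integer")
  if (!is.null(traversal_mode) &&
      !traversal_mode %in% c("directed", "undirected"))
    stop_config("traversal_mode must be 'directed' or 'undirected'")
  structure(list(beta_slack = as.numeric(beta_slack),
                 max_length = as.integer(max_length),
                 traversal_mode = traversal_mode),
            class = "search_config")
}

apply_mode <- function(graph, config) {
  if (!is.null(config$traversal_mode) &&
      !identical(config$traversal_mode, graph$traversal_mode)) {
    graph$traversal_mode <- config$traversal_mode
  }
  graph
}

#' Hop distances from every node to a fixed target
#'
#' Runs a heap-based Dijkstra pass (binary min-heap with insert, move-up
#' re-sort and in-heap membership test) over unit-length edges. In directed
#' mode expansion follows edges pointing to the settled node, so
#' `dist[u]` is the length of the shortest directed path u -> target; in
#' undirected mode neighbors are the union of both directions.
#'
#' @param graph an `association_graph`.
#' @param target a node id present in the graph.
#' @return An object of class `distance_map`: list with `target` and `dist`,
#'   a named numeric vector over all nodes (`Inf` marks unreachable nodes).
#' @export
shortest_distances_to_target <- function(graph, target) {
  it <- node_idx(graph, target)
  n <- length(graph$node_ids)
  dir <- expand_direction(graph, toward_target = TRUE)
  nbrs <- switch(dir, both = graph$nb_both, `in` = graph$nb_in)

  dist <- rep(Inf, n)
  heap <- integer(n)      # heap of node indices, keyed by dist
  pos <- integer(n)       # 0 = never inserted, -1 = settled, >0 = heap slot
  hsize <- 0L

  swap <- function(a, b) {
    tmp <- heap[a]; heap[a] <<- heap[b]; heap[b] <<- tmp
    pos[heap[a]] <<- a; pos[heap[b]] <<- b
  }
  move_up <- function(k) {
    while (k > 1L) {
      parent <- k %/% 2L
      if (dist[heap[parent]] <= dist[heap[k]]) break
      swap(parent, k); k <- parent
    }
  }
  move_down <- function(k) {
    repeat {
      l <- 2L * k; r <- l + 1L; m <- k
      if (l <= hsize && dist[heap[l]] < dist[heap[m]]) m <- l
      if (r <= hsize && dist[heap[r]] < dist[heap[m]]) m <- r
      if (m == k) break
      swap(k, m); k <- m
    }
  }
  insert <- function(u) {
    hsize <<- hsize + 1L; heap[hsize] <<- u; pos[u] <<- hsize
    move_up(hsize)
  }
  pop_min <- function() {
    u <- heap[1L]
    swap(1L, hsize); hsize <<- hsize - 1L
    pos[u] <<- -1L
    if (hsize > 0L) move_down(1L)
    u
  }

  dist[it] <- 0
  insert(it)
  while (hsize > 0L) {
    vmin <- pop_min()
    nd <- dist[vmin] + 1
    for (u in nbrs[[vmin]]) {
      if (pos[u] == -1L) next          # already settled
      if (nd < dist[u]) {
        dist[u] <- nd
        if (pos[u] > 0L) move_up(pos[u]) else insert(u)
      }
    }
  }
  names(dist) <- graph$node_ids
  structure(list(target = target, dist = dist), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  fin <- sum(is.finite(x$dist))
  cat(sprintf("<distance_map> target '%s': %d reachable of %d nodes, max hop %s\n",
              x$target, fin, length(x$dist),
              if (fin > 0) max(x$dist[is.finite(x$dist)]) else NA))
  invisible(x)
}

## ---- associations -----------------------------------------------------

new_association <- function(nodes, steps) {
  structure(list(nodes = nodes, steps = steps,
                 length = length(nodes) - 1L),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("<association> %s (length %d)\n",
              paste(x$nodes, collapse = "~"), x$length))
  invisible(x)
}

#' @export
format.association <- function(x, ...) paste(x$nodes, collapse = "~")

## per-hop predicate annotations for a node sequence; errors if a hop has no
## supporting edge under the traversal mode
path_steps <- function(graph, idx_seq) {
  if (length(idx_seq) < 2) return(list())
  lapply(seq_len(length(idx_seq) - 1L), function(k) {
    p <- edge_predicates(graph, idx_seq[k], idx_seq[k + 1L])
    if (length(p) == 0)
      stop_contract("no edge between '%s' and '%s'",
                    graph$node_ids[idx_seq[k]], graph$node_ids[idx_seq[k + 1L]])
    p
  })
}

assoc_from_indices <- function(graph, idx_seq) {
  new_association(graph$node_ids[idx_seq], path_steps(graph, idx_seq))
}

new_association_set <- function(source, target, associations, L_min,
                                beta_slack = NA_real_, max_length = NA_integer_) {
  structure(list(query = c(source = source, target = target),
                 associations = associations, L_min = L_min,
                 beta_slack = beta_slack, max_length = max_length),
            class = "association_set")
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("<association_set> %s -> %s: %d association(s), L_min = %s\n",
              x$query[["source"]], x$query[["target"]],
              length(x$associations),
              if (is.finite(x$L_min)) x$L_min else "Inf"))
  for (a in head(x$associations, 10)) cat(" ", format(a), "\n")
  if (length(x$associations) > 10)
    cat(sprintf("  ... %d more\n", length(x$associations) - 10))
  invisible(x)
}

#' @export
length.association_set <- function(x) length(x$associations)

#' Tabulate an association set
#'
#' @param x an `association_set`.
#' @param row.names,optional,... passed over from the generic (unused).
#' @return data.frame with columns `rank`, `length`, `path` (tilde-joined
#'   node sequence) and `predicates` (per-hop annotation sets).
#' @export
as.data.frame.association_set <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  if (length(x$associations) == 0)
    return(data.frame(rank = integer(), length = integer(),
                      path = character(), predicates = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    rank = seq_along(x$associations),
    length = vapply(x$associations, `[[`, integer(1), "length"),
    path = vapply(x$associations, format, character(1)),
    predicates = vapply(x$associations, function(a)
      paste(vapply(a$steps, paste, character(1), collapse = "|"),
            collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

## ---- bidirectional BFS ------------------------------------------------

#' One shortest association via bidirectional breadth-first search
#'
#' Expands frontiers alternately from source (forward) and target (backward,
#' along in-edges in directed mode). The search stops the first time the two
#' explored sets share a node; among all commonly explored nodes the one
#' minimising forward + backward depth (ties: lexicographically smallest id)
#' joins the two recorded frontier paths.
#'
#' @param graph an `association_graph`.
#' @param source,target node ids present in the graph.
#' @return An `association`, or `NULL` when target is unreachable.
#' @export
bidirectional_shortest_path <- function(graph, source, target) {
  is <- node_idx(graph, source)
  it <- node_idx(graph, target)
  if (is == it) return(new_association(source, list()))

  n <- length(graph$node_ids)
  fwd_dir <- expand_direction(graph, toward_target = FALSE)  # out / both
  bwd_dir <- expand_direction(graph, toward_target = TRUE)   # in / both
  dF <- rep(NA_integer_, n); dB <- rep(NA_integer_, n)
  pF <- integer(n); pB <- integer(n)
  dF[is] <- 0L; dB[it] <- 0L
  frontF <- is; frontB <- it

  expand <- function(front, d, p, dir) {
    nxt <- integer(0)
    for (v in front) {
      for (u in traversal_neighbors(graph, v, dir)) {
        if (is.na(d[u])) {
          d[u] <- d[v] + 1L
          p[u] <- v
          nxt <- c(nxt, u)
        }
      }
    }
    list(front = sort(unique(nxt)), d = d, p = p)
  }
  meet <- function() {
    cand <- which(!is.na(dF) & !is.na(dB))
    if (length(cand) == 0) return(NA_integer_)
    tot <- dF[cand] + dB[cand]
    cand <- cand[tot == min(tot)]
    cand[1L]  # indices follow lexicographic id order
  }

  repeat {
    if (length(frontF) == 0 && length(frontB) == 0) return(NULL)
    if (length(frontF) > 0) {
      r <- expand(frontF, dF, pF, fwd_dir)
      frontF <- r$front; dF <- r$d; pF <- r$p
      m <- meet()
      if (!is.na(m)) break
    }
    if (length(frontB) > 0) {
      r <- expand(frontB, dB, pB, bwd_dir)
      frontB <- r$front; dB <- r$d; pB <- r$p
      m <- meet()
      if (!is.na(m)) break
    }
  }

  left <- m
  while (left != is) { left <- pF[left]; m <- c(left, m) }
  right <- m[length(m)]
  while (right != it) { right <- pB[right]; m <- c(m, right) }
  assoc_from_indices(graph, m)
}

## ---- near-shortest enumeration ---------------------------------------

## largest admitted hop length: the shortest length L_min is always admitted;
## beyond it, lengths strictly below (1 + beta) * L_min qualify (integer
## bound computed with an epsilon guard against floating-point edge cases)
near_shortest_bound <- function(L_min, beta_slack) {
  below <- ceiling((1 + beta_slack) * L_min - 1e-9) - 1
  max(L_min, below)
}

#' Enumerate all near-shortest simple associations
#'
#' Depth-first search from the source carrying a visited indicator per node;
#' the association is extended from `s` to `u` only when
#' `d(s) + 1 + d'(u)` stays within the admitted length bound, where `d'` is
#' the all-to-target distance map (the pruning oracle). The returned set is
#' exactly the simple source-to-target paths whose hop length is admitted by
#' `config$beta_slack` and at most `config$max_length`.
#'
#' @param graph an `association_graph`.
#' @param source,target node ids present in the graph.
#' @param dmap a `distance_map` for `target` computed on the same graph and
#'   traversal mode (see [shortest_distances_to_target()]).
#' @param config a [search_config()].
#' @return An `association_set` (empty, with `L_min = Inf`, when the target
#'   is unreachable).
#' @export
enumerate_near_shortest <- function(graph, source, target, dmap,
                                    config = search_config()) {
  if (!inherits(dmap, "distance_map") || !identical(dmap$target, target))
    stop_contract("distance map was computed for target '%s', not '%s'",
                  if (inherits(dmap, "distance_map")) dmap$target else "?",
                  target)
  graph <- apply_mode(graph, config)
  is <- node_idx(graph, source)
  it <- node_idx(graph, target)
  n <- length(graph$node_ids)
  d <- unname(dmap$dist[graph$node_ids])

  L_min <- d[is]
  if (!is.finite(L_min))
    return(new_association_set(source, target, list(), Inf,
                               config$beta_slack, config$max_length))
  if (is == it)
    return(new_association_set(source, target,
                               list(new_association(source, list())), 0L,
                               config$beta_slack, config$max_length))

  cap <- min(near_shortest_bound(L_min, config$beta_slack), config$max_length)
  if (cap < L_min)
    return(new_association_set(source, target, list(), as.integer(L_min),
                               config$beta_slack, config$max_length))

  dir <- expand_direction(graph, toward_target = FALSE)  # out / both
  nbrs <- switch(dir, both = graph$nb_both, out = graph$nb_out)

  visited <- logical(n)
  path <- integer(cap + 1L)
  found <- list()
  nf <- 0L

  dfs <- function(s, depth) {
    if (s == it) {
      nf <<- nf + 1L
      found[[nf]] <<- path[seq_len(depth + 1L)]
      return(invisible())
    }
    for (u in nbrs[[s]]) {
      if (!visited[u] && depth + 1 + d[u] <= cap) {
        visited[u] <<- TRUE
        path[depth + 2L] <<- u
        dfs(u, depth + 1L)
        visited[u] <<- FALSE
      }
    }
    invisible()
  }
  visited[is] <- TRUE
  path[1L] <- is
  dfs(is, 0L)

  assocs <- lapply(found, function(sq) assoc_from_indices(graph, sq))
  new_association_set(source, target, assocs, as.integer(L_min),
                      config$beta_slack, config$max_length)
}

#' Rank an association set shortest-first
#'
#' Stable, deterministic total order: length ascending, then node-sequence
#' lexicographic.
#'
#' @param assoc_set an `association_set`.
#' @return The same set with `associations` re-ordered.
#' @export
rank_by_length <- function(assoc_set) {
  if (!inherits(assoc_set, "association_set"))
    stop_contract("expected an association_set")
  a <- assoc_set$associations
  if (length(a) > 1) {
    len <- vapply(a, `[[`, integer(1), "length")
    key <- vapply(a, function(x) paste(x$nodes, collapse = ""),
                  character(1))
    assoc_set$associations <- a[order(len, key, method = "radix")]
  }
  assoc_set
}
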