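## Indexed, typed, directed multigraph over biomedical entities.
## Node identity is exact string equality on (optionally CURIE-compacted) ids.

#' Entity categories recognised by the graph store
#'
#' @format Character vector of the seven node categories.
#' @export
ENTITY_CATEGORIES <- c("compound", "drug", "gene", "disease",
                       "side_effect", "pathway", "other")

#' Construct an association graph from an edge table
#'
#' Builds the indexed multigraph used by the path-search stage. Edges are
#' de-duplicated on (source, target, predicate); provenance tags of collapsed
#' duplicates are merged. Self-loops are stored but never traversed.
#'
#' @param edges data.frame with character columns `source`, `target`,
#'   `predicate` and optionally `provenance`.
#' @param nodes optional character vector of node ids to include even when
#'   isolated (ids occurring in `edges` are always included).
#' @param categories optional named character vector id -> category; nodes
#'   without an entry default to `"other"`.
#' @param labels optional named character vector id -> display label.
#' @param traversal_mode `"undirected"` (default: neighbor expansion unions
#'   out- and in-neighbors) or `"directed"`.
#' @return An object of class `association_graph`.
#' @export
association_graph <- function(edges, nodes = NULL, categories = NULL,
                              labels = NULL,
                              traversal_mode = c("undirected", "directed")) {
  traversal_mode <- match.arg(traversal_mode)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        predicate = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "predicate")
  if (!all(need %in% names(edges)))
    stop_contract("edge table must have columns source, target, predicate")
  if (is.null(edges$provenance)) edges$provenance <- rep(NA_character_, nrow(edges))
  for (cl in c(need, "provenance")) edges[[cl]] <- as.character(edges[[cl]])
  if (nrow(edges) > 0 &&
      any(!nzchar(edges$source) | !nzchar(edges$target) | !nzchar(edges$predicate)))
    stop_data("empty node id or predicate in edge table")

  ## collapse duplicate (s, t, p) triples, merging provenance tags
  if (nrow(edges) > 0) {
    key <- paste(edges$source, edges$target, edges$predicate, sep = "\r")
    if (anyDuplicated(key)) {
      prov <- vapply(split(edges$provenance, key), function(p) {
        p <- sort(unique(p[!is.na(p) & nzchar(p)]))
        if (length(p) == 0) NA_character_ else paste(p, collapse = ";")
      }, character(1))
      edges <- edges[!duplicated(key), , drop = FALSE]
      edges$provenance <- unname(prov[paste(edges$source, edges$target,
                                            edges$predicate, sep = "\r")])
    }
    edges <- edges[order(edges$source, edges$predicate, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }

  node_ids <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  if (any(!nzchar(node_ids))) stop_data("empty node id")
  n <- length(node_ids)
  node_index <- seq_len(n)
  names(node_index) <- node_ids

  cats <- rep("other", n)
  names(cats) <- node_ids
  if (!is.null(categories)) {
    categories <- categories[names(categories) %in% node_ids]
    bad <- setdiff(unique(categories), ENTITY_CATEGORIES)
    if (length(bad) > 0)
      stop_config("unknown entity category: %s", paste(bad, collapse = ", "))
    cats[names(categories)] <- unname(categories)
  }
  labs <- rep(NA_character_, n)
  names(labs) <- node_ids
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% node_ids]
    labs[names(labels)] <- unname(labels)
  }

  si <- unname(node_index[edges$source])
  ti <- unname(node_index[edges$target])

  ## adjacency lists as sorted unique integer neighbor vectors (index order
  ## coincides with lexicographic id order); self-loops excluded so they are
  ## never traversed
  nb_out <- rep(list(integer(0)), n)
  nb_in <- rep(list(integer(0)), n)
  keep <- si != ti
  if (any(keep)) {
    so <- split(ti[keep], si[keep])
    for (k in names(so)) nb_out[[as.integer(k)]] <- sort(unique(so[[k]]))
    sn <- split(si[keep], ti[keep])
    for (k in names(sn)) nb_in[[as.integer(k)]] <- sort(unique(sn[[k]]))
  }
  nb_both <- lapply(node_index, function(i) sort(unique(c(nb_out[[i]], nb_in[[i]]))))

  ## predicate lookup: "si\rti" -> character vector of predicates
  pred_map <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) {
    pm <- split(edges$predicate, paste(si, ti, sep = "\r"))
    for (k in names(pm)) assign(k, sort(unique(pm[[k]])), envir = pred_map)
  }

  structure(list(node_ids = node_ids, node_index = node_index,
                 categories = cats, labels = labs, edges = edges,
                 si = si, ti = ti,
                 nb_out = nb_out, nb_in = nb_in, nb_both = nb_both,
                 pred_map = pred_map, traversal_mode = traversal_mode),
            class = "association_graph")
}

#' @export
print.association_graph <- function(x, ...) {
  cat(sprintf("<association_graph> %d nodes, %d edges (%s traversal)\n",
              length(x$node_ids), nrow(x$edges), x$traversal_mode))
  tab <- table(x$categories)
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

node_idx <- function(graph, node) {
  i <- graph$node_index[node]
  if (length(i) != 1 || is.na(i))
    stop_data("node '%s' not found in graph", node)
  unname(i)
}

## neighbor indices used for traversal; `direction` is the expansion
## direction: "out" follows out-edges, "in" follows edges pointing at the node
traversal_neighbors <- function(graph, i, direction) {
  switch(direction,
         out = graph$nb_out[[i]],
         `in` = graph$nb_in[[i]],
         both = graph$nb_both[[i]])
}

## expansion direction toward the target given the traversal mode
expand_direction <- function(graph, toward_target = TRUE) {
  if (graph$traversal_mode == "undirected") return("both")
  if (toward_target) "in" else "out"
}

#' List the adjacency of one node
#'
#' Returns the indexed adjacency for the requested direction, sorted by
#' (predicate, neighbor id) for deterministic output.
#'
#' @param graph an `association_graph`.
#' @param node a node id present in the graph.
#' @param direction `"out"`, `"in"` or `"both"` (union, de-duplicated).
#' @return data.frame with columns `predicate`, `neighbor`.
#' @export
neighbors_of <- function(graph, node, direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  node_idx(graph, node)  # lookup error for unknown node
  e <- graph$edges
  out <- e[e$source == node, c("predicate", "target")]
  names(out) <- c("predicate", "neighbor")
  inc <- e[e$target == node, c("predicate", "source")]
  names(inc) <- c("predicate", "neighbor")
  adj <- switch(direction, out = out, `in` = inc, both = rbind(out, inc))
  adj <- unique(adj)
  adj <- adj[order(adj$predicate, adj$neighbor), , drop = FALSE]
  rownames(adj) <- NULL
  adj
}

## predicates annotating the hop a -> b under the graph's traversal mode
edge_predicates <- function(graph, ia, ib) {
  p <- pred_map_get(graph, ia, ib)
  if (graph$traversal_mode == "undirected")
    p <- sort(unique(c(p, pred_map_get(graph, ib, ia))))
  p
}

pred_map_get <- function(graph, ia, ib) {
  k <- paste(ia, ib, sep = "\r")
  if (exists(k, envir = graph$pred_map, inherits = FALSE))
    get(k, envir = graph$pred_map, inherits = FALSE)
  else character(0)
}

#' Load a triple file into an association graph
#'
#' Reads N-Triples or 3/4-column delimited text (subject, predicate,
#' object\[, provenance\]) and builds the indexed graph. IRIs are compacted
#' to CURIEs via `prefix_map` before indexing. Only entity-entity triples
#' enter the traversal graph; literal-valued N-Triples objects are kept as
#' node labels.
#'
#' @param source file path or character vector of lines.
#' @param format `"tsv"` or `"ntriples"` (must be named explicitly).
#' @param category_map named character vector id -> category, or `NULL`.
#' @param prefix_map named character vector prefix -> IRI base, or `NULL`.
#' @param traversal_mode `"undirected"` or `"directed"`.
#' @return An `association_graph`.
#' @export
load_triples <- function(source, format, category_map = NULL,
                         prefix_map = NULL,
                         traversal_mode = c("undirected", "directed")) {
  traversal_mode <- match.arg(traversal_mode)
  if (missing(format) || !is.character(format) || length(format) != 1 ||
      !format %in% c("tsv", "ntriples"))
    stop_config("format must be one of 'tsv', 'ntriples'")
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)

  if (format == "tsv") {
    parsed <- parse_tsv_triples(lines)
  } else {
    parsed <- parse_ntriples(lines, prefix_map)
  }
  association_graph(parsed$edges, categories = category_map,
                    labels = parsed$labels, traversal_mode = traversal_mode)
}

parse_tsv_triples <- function(lines) {
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(parts)
  ## a trailing empty provenance column ("a\tb\tc\t") splits to 3 parts; pad
  bad <- which(ncol < 3 | ncol > 4)
  if (length(bad) > 0)
    stop_data("malformed triple line %d: expected 3 or 4 tab-separated columns, got %d",
              keep[bad[1]], ncol[bad[1]])
  src <- vapply(parts, `[[`, character(1), 1)
  prd <- vapply(parts, `[[`, character(1), 2)
  obj <- vapply(parts, `[[`, character(1), 3)
  prov <- vapply(parts, function(p)
    if (length(p) >= 4 && nzchar(p[[4]])) p[[4]] else NA_character_,
    character(1))
  list(edges = data.frame(source = src, target = obj, predicate = prd,
                          provenance = prov, stringsAsFactors = FALSE),
       labels = NULL)
}

NT_TERM <- "(<[^<>\"]*>|_:[A-Za-z0-9_.]+)"
NT_LITERAL <- "(\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^<>]*>|@[A-Za-z0-9-]+)?)"

parse_ntriples <- function(lines, prefix_map = NULL) {
  pat <- paste0("^\\s*", NT_TERM, "\\s+", "(<[^<>\"]*>)", "\\s+",
                "(?:", NT_TERM, "|", NT_LITERAL, ")", "\\s*\\.\\s*$")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  src <- prd <- obj <- character(0)
  lab_id <- lab_val <- character(0)
  for (ln in keep) {
    m <- regmatches(lines[ln], regexec(pat, lines[ln], perl = TRUE))[[1]]
    if (length(m) == 0)
      stop_data("malformed N-Triples line %d", ln)
    s <- compact_iri(m[2], prefix_map)
    p <- compact_iri(m[3], prefix_map)
    ent <- m[4]
    lit <- m[5]
    if (nzchar(ent)) {
      src <- c(src, s); prd <- c(prd, p); obj <- c(obj, compact_iri(ent, prefix_map))
    } else {
      ## literal object: keep as a label for the subject, do not create a node
      v <- sub("^\"", "", sub("\"(\\^\\^<[^<>]*>|@[A-Za-z0-9-]+)?$", "", lit))
      lab_id <- c(lab_id, s); lab_val <- c(lab_val, v)
    }
  }
  labels <- NULL
  if (length(lab_id) > 0) {
    first <- !duplicated(lab_id)
    labels <- lab_val[first]
    names(labels) <- lab_id[first]
  }
  list(edges = data.frame(source = src, target = obj, predicate = prd,
                          provenance = NA_character_, stringsAsFactors = FALSE),
       labels = labels)
}

## compact an IRI (or pass a blank node / already-compact id through) to a
## CURIE using the longest matching prefix base
compact_iri <- function(term, prefix_map = NULL) {
  if (!startsWith(term, "<")) return(term)
  iri <- substr(term, 2, nchar(term) - 1)
  if (!is.null(prefix_map) && length(prefix_map) > 0) {
    hit <- which(startsWith(iri, unname(prefix_map)))
    if (length(hit) > 0) {
      best <- hit[which.max(nchar(prefix_map[hit]))]
      return(paste0(names(prefix_map)[best], ":",
                    substr(iri, nchar(prefix_map[best]) + 1, nchar(iri))))
    }
  }
  iri
}

#' Read a two-column TSV mapping file
#'
#' `read_category_map()` reads id -> category pairs; `read_prefix_map()`
#' reads prefix -> IRI-base pairs. Both return named character vectors.
#'
#' @param path file path.
#' @return Named character vector.
#' @export
read_category_map <- function(path) read_two_col(path, "category map")

#' @rdname read_category_map
#' @export
read_prefix_map <- function(path) read_two_col(path, "prefix map")

read_two_col <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    stop_data("malformed %s line %d: expected 2 tab-separated columns",
              what, bad[1])
  out <- vapply(parts, `[[`, character(1), 2)
  names(out) <- vapply(parts, `[[`, character(1), 1)
  out
}

#' Write the canonical TSV dump of a graph
#'
#' Emits one `source<TAB>predicate<TAB>object<TAB>provenance` line per edge,
#' sorted; reloading the dump with [load_triples()] yields an identical graph
#' (for graphs without isolated nodes).
#'
#' @param graph an `association_graph`.
#' @param path output file path, or `"-"` for standard output.
#' @return Invisibly, the lines written.
#' @export
write_triples <- function(graph, path) {
  e <- graph$edges
  prov <- ifelse(is.na(e$provenance), "", e$provenance)
  lines <- paste(e$source, e$predicate, e$target, prov, sep = "\t")
  if (identical(path, "-")) cat(lines, sep = "\n")
  else writeLines(lines, path)
  invisible(lines)
}

#' Compare two association graphs
#'
#' @param target,current graphs to compare.
#' @param ... unused.
#' @return `TRUE`, or a character vector of differences.
#' @method all.equal association_graph
#' @export
all.equal.association_graph <- function(target, current, ...) {
  msg <- character(0)
  if (!identical(target$node_ids, current$node_ids)) msg <- c(msg, "node sets differ")
  te <- target$edges[, c("source", "predicate", "target", "provenance")]
  ce <- current$edges[, c("source", "predicate", "target", "provenance")]
  if (!identical(te, ce)) msg <- c(msg, "edge sets differ")
  if (!identical(target$traversal_mode, current$traversal_mode))
    msg <- c(msg, "traversal modes differ")
  if (length(msg) == 0) TRUE else msg
}
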