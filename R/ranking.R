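## Topic-coherence scoring of associations: the score of a path is the
## accumulated symmetric KL divergence between the topic distributions of
## consecutive bio-terms on it. Smaller scores mean more thematically
## coherent paths; ranking puts the smallest score on top.

#' Score one association by accumulated (symmetric) KL divergence
#'
#' The bio-term chain is the ordered subsequence of path nodes that map to
#' modeled bio-terms (with `node_to_bioterm = NULL`, a node maps to itself
#' when it has a `theta` row). Annotation nodes that are not bio-terms
#' contribute nothing. The score sums `symmetric_kl(theta_a, theta_b)` over
#' consecutive chain pairs (path direction is not evaluated); with
#' `directed = TRUE` the non-symmetric `kl_divergence` is accumulated in
#' path order instead. The association is `unscored` when the chain has
#' fewer than two members or an explicitly mapped bio-term lacks a `theta`
#' row; the synthetic background term never enters a chain.
#'
#' @param assoc an `association`.
#' @param model a `biolda_model`.
#' @param node_to_bioterm optional named character vector node id ->
#'   bio-term id (`NA` or absent = not a bio-term); `NULL` means node ids
#'   are themselves bio-term ids.
#' @param directed accumulate non-symmetric KL in path order instead of the
#'   symmetric divergence.
#' @return Object of class `scored_association`: the association plus
#'   `bioterm_chain`, `step_scores`, `score`, `status`.
#' @export
score_association <- function(assoc, model, node_to_bioterm = NULL,
                              directed = FALSE) {
  if (!inherits(assoc, "association")) stop_contract("expected an association")
  if (!inherits(model, "biolda_model")) stop_contract("expected a biolda_model")
  known <- rownames(model$theta)

  missing_row <- FALSE
  if (is.null(node_to_bioterm)) {
    chain <- assoc$nodes[assoc$nodes %in% known]
  } else {
    mapped <- node_to_bioterm[assoc$nodes]
    chain <- unname(mapped[!is.na(mapped)])
    missing_row <- any(!chain %in% known)
  }
  chain <- chain[chain != BACKGROUND_BIOTERM]

  if (length(chain) < 2 || missing_row) {
    return(structure(list(association = assoc, bioterm_chain = chain,
                          step_scores = numeric(0), score = NA_real_,
                          status = "unscored"),
                     class = "scored_association"))
  }
  div <- if (directed) kl_divergence else symmetric_kl
  steps <- vapply(seq_len(length(chain) - 1L), function(k)
    div(model$theta[chain[k], ], model$theta[chain[k + 1L], ]),
    numeric(1))
  structure(list(association = assoc, bioterm_chain = chain,
                 step_scores = steps, score = sum(steps),
                 status = "scored"),
            class = "scored_association")
}

#' @export
print.scored_association <- function(x, ...) {
  cat(sprintf("<scored_association> %s | chain %s | %s\n",
              format(x$association),
              paste(x$bioterm_chain, collapse = "~"),
              if (x$status == "scored") sprintf("sKL = %.6f", x$score)
              else "unscored"))
  invisible(x)
}

#' Rank associations by topic-coherence score
#'
#' Scored associations come first, sorted by (score ascending, hop length
#' ascending, node-sequence lexicographic); unscored associations follow in
#' (length, lexicographic) order unless dropped. The result is truncated to
#' `top_k`.
#'
#' @param assocs list of `association` objects, or an `association_set`.
#' @param model a `biolda_model`.
#' @param node_to_bioterm see [score_association()].
#' @param top_k maximum number of results (>= 1).
#' @param directed use the directed (non-symmetric) accumulated score.
#' @param drop_unscored drop unscored associations instead of appending them.
#' @return List of `scored_association` objects.
#' @export
rank_associations <- function(assocs, model, node_to_bioterm = NULL,
                              top_k = 20L, directed = FALSE,
                              drop_unscored = FALSE) {
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 1)
    stop_config("top_k must be a positive integer")
  if (inherits(assocs, "association_set")) assocs <- assocs$associations
  scored <- lapply(assocs, score_association, model = model,
                   node_to_bioterm = node_to_bioterm, directed = directed)
  if (length(scored) == 0) return(scored)

  status <- vapply(scored, `[[`, character(1), "status")
  len <- vapply(scored, function(s) s$association$length, integer(1))
  key <- vapply(scored, function(s)
    paste(s$association$nodes, collapse = ""), character(1))
  sc <- vapply(scored, `[[`, numeric(1), "score")

  ok <- which(status == "scored")
  un <- which(status == "unscored")
  ok <- ok[order(sc[ok], len[ok], key[ok], method = "radix")]
  un <- un[order(len[un], key[un], method = "radix")]
  out <- scored[if (drop_unscored) ok else c(ok, un)]
  head(out, as.integer(top_k))
}

#' Tabulate ranked associations
#'
#' @param scored list of `scored_association` objects (from
#'   [rank_associations()]).
#' @return data.frame with columns `rank`, `score`, `length`,
#'   `bioterm_chain` and `path` (tilde-joined), mirroring the ranked-path
#'   tables the search tool prints.
#' @export
scored_association_table <- function(scored) {
  if (length(scored) == 0)
    return(data.frame(rank = integer(), score = numeric(),
                      length = integer(), bioterm_chain = character(),
                      path = character(), stringsAsFactors = FALSE))
  data.frame(
    rank = seq_along(scored),
    score = vapply(scored, `[[`, numeric(1), "score"),
    length = vapply(scored, function(s) s$association$length, integer(1)),
    bioterm_chain = vapply(scored, function(s)
      paste(s$bioterm_chain, collapse = "~"), character(1)),
    path = vapply(scored, function(s) format(s$association), character(1)),
    stringsAsFactors = FALSE)
}
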