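## Bio-LDA: an author-topic-style LDA in which every token is attributed to
## one of its document's tagged bio-terms; the bio-term selects a topic, the
## topic generates the word and the document's journal stamp. Inference is
## collapsed Gibbs sampling (C++ kernel); estimators are Dirichlet-smoothed
## posterior means.

BACKGROUND_BIOTERM <- "__BG__"

#' Tag bio-terms in a token sequence by dictionary lookup
#'
#' Case-insensitive, longest-match-first, non-overlapping matching of
#' (possibly multi-word) dictionary terms against the token sequence.
#'
#' @param tokens character vector of word tokens.
#' @param dictionary named character vector mapping lowercase term strings
#'   (single- or multi-word, space-separated) to canonical bio-term ids.
#' @return Sorted character vector of matched ids (possibly empty).
#' @export
tag_bioterms <- function(tokens, dictionary) {
  if (length(tokens) == 0 || length(dictionary) == 0) return(character(0))
  toks <- tolower(tokens)
  max_words <- max(lengths(strsplit(names(dictionary), " ", fixed = TRUE)))
  hits <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    matched <- 0L
    for (k in seq(min(max_words, n - i + 1L), 1L)) {
      phrase <- paste(toks[i:(i + k - 1L)], collapse = " ")
      if (!is.na(dictionary[phrase])) {
        hits <- c(hits, unname(dictionary[phrase]))
        matched <- k
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  sort(unique(hits))
}

#' Read a term dictionary (2-column TSV: term, id)
#'
#' @param path file path.
#' @return Named character vector, lowercase term -> id.
#' @export
read_dictionary <- function(path) {
  m <- read_two_col(path, "dictionary")
  names(m) <- tolower(names(m))
  m
}

#' Build an indexed corpus from document records
#'
#' Tokens are lowercased; stopwords and words occurring fewer than
#' `min_word_count` times corpus-wide are removed from the vocabulary (and
#' from the documents). Documents left without tokens are dropped. Documents
#' whose bio-term set is empty (after optional dictionary tagging) receive
#' the synthetic background bio-term `"__BG__"` so the uniform bio-term draw
#' is always well defined.
#'
#' @param records data.frame (or list of lists) with fields `tokens`
#'   (space-separated string or character vector), `bioterms`
#'   (comma-separated string or character vector, may be empty) and
#'   `journal`.
#' @param dictionaries optional named character vector (term -> id); when
#'   given, records with empty `bioterms` are tagged from their tokens.
#' @param stopwords character vector of words to drop.
#' @param min_word_count minimum corpus-wide frequency for a word to enter
#'   the vocabulary.
#' @return An object of class `biolda_corpus`: documents (token/bioterm
#'   indices + journal index), `vocabulary`, `bioterms`, `journals`.
#' @export
build_corpus <- function(records, dictionaries = NULL,
                         stopwords = character(), min_word_count = 1L) {
  docs <- normalize_records(records)
  if (length(docs) == 0) stop_config("no documents supplied")

  for (i in seq_along(docs)) {
    docs[[i]]$tokens <- tolower(docs[[i]]$tokens)
    if (length(docs[[i]]$bioterms) == 0 && !is.null(dictionaries))
      docs[[i]]$bioterms <- tag_bioterms(docs[[i]]$tokens, dictionaries)
    if (length(docs[[i]]$bioterms) == 0)
      docs[[i]]$bioterms <- BACKGROUND_BIOTERM
  }

  all_tokens <- unlist(lapply(docs, `[[`, "tokens"))
  counts <- table(all_tokens)
  vocab <- sort(names(counts)[counts >= min_word_count])
  vocab <- setdiff(vocab, tolower(stopwords))
  if (length(vocab) == 0)
    stop_config("empty vocabulary after stopword and frequency filtering")

  keep <- logical(length(docs))
  for (i in seq_along(docs)) {
    docs[[i]]$tokens <- docs[[i]]$tokens[docs[[i]]$tokens %in% vocab]
    keep[i] <- length(docs[[i]]$tokens) > 0
  }
  docs <- docs[keep]
  if (length(docs) == 0)
    stop_config("no documents left after filtering")

  bioterms <- sort(unique(unlist(lapply(docs, `[[`, "bioterms"))))
  journals <- sort(unique(vapply(docs, `[[`, character(1), "journal")))
  vidx <- seq_along(vocab); names(vidx) <- vocab
  bidx <- seq_along(bioterms); names(bidx) <- bioterms
  jidx <- seq_along(journals); names(jidx) <- journals

  documents <- lapply(docs, function(d) {
    list(tokens = unname(vidx[d$tokens]),
         bioterms = sort(unname(bidx[d$bioterms])),
         journal = unname(jidx[[d$journal]]))
  })
  structure(list(documents = documents, vocabulary = vocab,
                 bioterms = bioterms, journals = journals),
            class = "biolda_corpus")
}

normalize_records <- function(records) {
  split_field <- function(x, sep) {
    if (length(x) > 1) return(as.character(x))
    x <- trimws(as.character(x))
    if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
    trimws(strsplit(x, sep)[[1]])
  }
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  }
  lapply(records, function(r) {
    if (is.null(r$tokens) || is.null(r$journal))
      stop_data("document record must have fields tokens and journal")
    list(tokens = split_field(r$tokens, "\\s+"),
         bioterms = split_field(r$bioterms, "\\s*,\\s*"),
         journal = as.character(r$journal))
  })
}

#' @export
print.biolda_corpus <- function(x, ...) {
  cat(sprintf(
    "<biolda_corpus> %d documents, %d tokens, vocab %d, %d bio-terms, %d journals\n",
    length(x$documents), sum(vapply(x$documents, function(d)
      length(d$tokens), integer(1))),
    length(x$vocabulary), length(x$bioterms), length(x$journals)))
  invisible(x)
}

#' Read / write corpus record files
#'
#' One record per line, three tab-separated fields: space-separated tokens,
#' comma-separated bio-term ids (may be empty), journal id.
#'
#' @param path file path.
#' @return `read_corpus_records()`: data.frame with columns `tokens`,
#'   `bioterms`, `journal` suitable for [build_corpus()].
#' @export
read_corpus_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop_data("malformed corpus record line %d: expected 3 tab-separated fields",
              bad[1])
  data.frame(
    tokens = vapply(parts, `[[`, character(1), 1),
    bioterms = vapply(parts, `[[`, character(1), 2),
    journal = vapply(parts, `[[`, character(1), 3),
    stringsAsFactors = FALSE)
}

#' @rdname read_corpus_records
#' @param records data.frame with columns `tokens`, `bioterms`, `journal`.
#' @export
write_corpus_records <- function(records, path) {
  writeLines(paste(records$tokens, records$bioterms, records$journal,
                   sep = "\t"), path)
  invisible(path)
}

#' Bio-LDA hyperparameters
#'
#' Defaults follow the usual LDA convention `alpha = 50 / n_topics` with
#' `beta_word = 0.01` (topic-word smoothing) and `mu = 0.1` (topic-journal
#' smoothing).
#'
#' @param n_topics number of topics T (>= 1).
#' @param alpha Dirichlet prior on bio-term -> topic rows.
#' @param beta_word Dirichlet prior on topic -> word rows.
#' @param mu Dirichlet prior on topic -> journal rows.
#' @return Object of class `biolda_hyperparameters`.
#' @export
biolda_hyperparameters <- function(n_topics, alpha = 50 / n_topics,
                                   beta_word = 0.01, mu = 0.1) {
  if (!is.numeric(n_topics) || length(n_topics) != 1 || n_topics < 1)
    stop_config("n_topics must be a positive integer")
  if (alpha <= 0 || beta_word <= 0 || mu <= 0)
    stop_config("Dirichlet priors must be strictly positive")
  structure(list(n_topics = as.integer(n_topics), alpha = alpha,
                 beta_word = beta_word, mu = mu),
            class = "biolda_hyperparameters")
}

#' Collapsed Gibbs sampling for Bio-LDA
#'
#' Jointly resamples each token's (bio-term, topic) pair from the collapsed
#' conditional -- the product of the smoothed bio-term/topic, topic/word and
#' topic/journal count ratios with the current token excluded -- with the
#' bio-term restricted (uniform prior) to the document's tagged set. Returns
#' the final sampler state; identical seeds give identical states.
#'
#' @param corpus a `biolda_corpus`.
#' @param hp a [biolda_hyperparameters()] object.
#' @param sweeps number of full Gibbs sweeps (> `burn_in`).
#' @param burn_in sweeps to discard (recorded on the state for downstream
#'   use; the returned counts are the final-sweep state).
#' @param seed integer seed controlling all sampler randomness.
#' @param keep_trace if `TRUE`, also return the per-sweep topic assignment
#'   matrix (sweeps x tokens; only sensible for tiny corpora).
#' @return Object of class `biolda_state` with assignment vectors `z`, `x`,
#'   count matrices `n_bt` (bio-term x topic), `n_tw` (topic x word),
#'   `n_tj` (topic x journal), and bookkeeping fields.
#' @export
gibbs_sample <- function(corpus, hp, sweeps = 500L, burn_in = 100L, seed = 1L,
                         keep_trace = FALSE) {
  if (!inherits(corpus, "biolda_corpus")) stop_contract("expected a biolda_corpus")
  if (!inherits(hp, "biolda_hyperparameters"))
    stop_config("expected biolda_hyperparameters")
  if (sweeps <= burn_in || burn_in < 0)
    stop_config("need sweeps > burn_in >= 0")

  docs <- corpus$documents
  doc_of <- rep(seq_along(docs),
                vapply(docs, function(d) length(d$tokens), integer(1)))
  word_of <- unlist(lapply(docs, `[[`, "tokens"))
  journal_of_doc <- vapply(docs, `[[`, integer(1), "journal")
  bd <- lapply(docs, function(d) as.integer(d$bioterms - 1L))
  if (any(lengths(bd) == 0))
    stop_contract("every document must carry at least one bio-term")

  B <- length(corpus$bioterms); T <- hp$n_topics
  W <- length(corpus$vocabulary); J <- length(corpus$journals)

  set.seed(as.integer(seed))
  res <- gibbs_sampler_cpp(as.integer(doc_of - 1L), as.integer(word_of - 1L),
                           as.integer(journal_of_doc - 1L), bd,
                           B, as.integer(T), W, J,
                           hp$alpha, hp$beta_word, hp$mu,
                           as.integer(sweeps), isTRUE(keep_trace))

  dimnames(res$n_bt) <- list(corpus$bioterms, NULL)
  dimnames(res$n_tw) <- list(NULL, corpus$vocabulary)
  dimnames(res$n_tj) <- list(NULL, corpus$journals)
  state <- list(z = res$z + 1L, x = res$x + 1L,
                doc_of = doc_of, word_of = word_of,
                journal_of_doc = journal_of_doc,
                n_bt = res$n_bt, n_tw = res$n_tw, n_tj = res$n_tj,
                sweeps = as.integer(sweeps), burn_in = as.integer(burn_in),
                rng_seed = as.integer(seed))
  if (isTRUE(keep_trace)) state$trace_z <- res$trace_z + 1L
  structure(state, class = "biolda_state")
}

#' @export
print.biolda_state <- function(x, ...) {
  cat(sprintf("<biolda_state> %d tokens, %d topics, %d sweeps (burn-in %d), seed %d\n",
              length(x$z), ncol(x$n_bt), x$sweeps, x$burn_in, x$rng_seed))
  invisible(x)
}

#' Estimate the smoothed Bio-LDA distributions from a sampler state
#'
#' Each distribution is the Dirichlet-smoothed posterior mean
#' `(count + prior) / (row total + dimension * prior)`:
#' `theta` (bio-term x topic), `phi` (topic x word), `psi` (topic x journal).
#' Rows sum to one and all entries are strictly positive.
#'
#' @param state a `biolda_state`.
#' @param corpus the `biolda_corpus` the state was sampled on.
#' @param hp the [biolda_hyperparameters()] used.
#' @return Object of class `biolda_model` with matrices `theta`, `phi`,
#'   `psi`.
#' @export
estimate_distributions <- function(state, corpus, hp) {
  T <- hp$n_topics
  if (ncol(state$n_bt) != T || nrow(state$n_tw) != T || nrow(state$n_tj) != T)
    stop_contract("sampler state has %d topics, hyperparameters say %d",
                  ncol(state$n_bt), T)
  if (nrow(state$n_bt) != length(corpus$bioterms) ||
      ncol(state$n_tw) != length(corpus$vocabulary) ||
      ncol(state$n_tj) != length(corpus$journals))
    stop_contract("sampler state dimensions do not match corpus")

  smooth_rows <- function(counts, prior) {
    (counts + prior) / (rowSums(counts) + ncol(counts) * prior)
  }
  theta <- smooth_rows(state$n_bt, hp$alpha)
  phi <- smooth_rows(state$n_tw, hp$beta_word)
  psi <- smooth_rows(state$n_tj, hp$mu)
  colnames(theta) <- paste0("topic", seq_len(T))
  rownames(phi) <- rownames(psi) <- paste0("topic", seq_len(T))
  structure(list(theta = theta, phi = phi, psi = psi),
            class = "biolda_model")
}

#' @export
print.biolda_model <- function(x, ...) {
  cat(sprintf("<biolda_model> %d bio-terms x %d topics; vocab %d; %d journals\n",
              nrow(x$theta), ncol(x$theta), ncol(x$phi), ncol(x$psi)))
  invisible(x)
}

#' Fit a Bio-LDA model (sampling + estimation)
#'
#' @inheritParams gibbs_sample
#' @param n_topics number of topics (used when `hp` is not supplied).
#' @param hp optional [biolda_hyperparameters()]; overrides `n_topics`.
#' @return Object of class `biolda_fit`: `model`, `state`, `hp`.
#' @export
biolda_train <- function(corpus, n_topics, sweeps = 500L, burn_in = 100L,
                         seed = 1L, hp = NULL) {
  if (is.null(hp)) hp <- biolda_hyperparameters(n_topics)
  state <- gibbs_sample(corpus, hp, sweeps = sweeps, burn_in = burn_in,
                        seed = seed)
  model <- estimate_distributions(state, corpus, hp)
  structure(list(model = model, state = state, hp = hp),
            class = "biolda_fit")
}

## ---- information-theoretic measures ----------------------------------

check_prob <- function(p, arg = "p", tol = 1e-8) {
  if (!is.numeric(p) || any(p < 0))
    stop_contract("%s must be a non-negative numeric vector", arg)
  if (abs(sum(p) - 1) > tol)
    stop_contract("%s does not sum to 1 (sum = %.12g)", arg, sum(p))
  invisible(p)
}

#' Shannon entropy of a bio-term's topic distribution
#'
#' Natural-log entropy `-sum(p log p)` with `0 log 0 = 0`. High entropy means
#' the bio-term spreads over many topics; a point mass has entropy 0.
#'
#' @param theta_row probability vector (a row of the model's `theta`).
#' @return Non-negative scalar (nats).
#' @export
bioterm_entropy <- function(theta_row) {
  check_prob(theta_row, "theta_row")
  p <- theta_row[theta_row > 0]
  -sum(p * log(p))
}

#' Kullback-Leibler divergence between two topic distributions
#'
#' `sum(p log(p / q))` in natural log; non-negative, zero iff `p == q`.
#' `q` must be strictly positive (which smoothed model rows always are).
#'
#' @param p,q probability vectors of equal length.
#' @return Non-negative scalar (nats).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop_contract("p and q have different lengths (%d vs %d)",
                  length(p), length(q))
  check_prob(p, "p")
  if (any(q <= 0)) stop_contract("q must be strictly positive")
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

#' Symmetric KL divergence
#'
#' `kl_divergence(p, q) + kl_divergence(q, p)`; the per-step cost in
#' association scoring. Smaller values mean more thematically related
#' bio-terms.
#'
#' @inheritParams kl_divergence
#' @return Non-negative scalar (nats).
#' @export
symmetric_kl <- function(p, q) kl_divergence(p, q) + kl_divergence(q, p)

## ---- model persistence ------------------------------------------------

#' Write / read a Bio-LDA model archive
#'
#' The archive is a directory holding `theta.tsv`, `phi.tsv`, `psi.tsv`
#' (full-precision, so models round-trip bit-exactly) and a plain-text
#' `MANIFEST` recording dimensions, hyperparameters, seed and sweep count.
#'
#' @param fit a `biolda_fit` (or a bare `biolda_model`, in which case
#'   manifest fields about the sampler are omitted).
#' @param dir directory to create/overwrite.
#' @return `write_biolda_model()`: the directory, invisibly;
#'   `read_biolda_model()`: a `biolda_model`.
#' @export
write_biolda_model <- function(fit, dir) {
  model <- if (inherits(fit, "biolda_fit")) fit$model else fit
  if (!inherits(model, "biolda_model")) stop_contract("expected a biolda model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    lines <- c(paste(c("", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                       collapse = "\t"), character(1)))
    writeLines(lines, file.path(dir, f))
  }
  wm(model$theta, "theta.tsv")
  wm(model$phi, "phi.tsv")
  wm(model$psi, "psi.tsv")
  man <- c(sprintf("bioterms: %d", nrow(model$theta)),
           sprintf("topics: %d", ncol(model$theta)),
           sprintf("vocabulary: %d", ncol(model$phi)),
           sprintf("journals: %d", ncol(model$psi)))
  if (inherits(fit, "biolda_fit")) {
    man <- c(man,
             sprintf("alpha: %.17g", fit$hp$alpha),
             sprintf("beta_word: %.17g", fit$hp$beta_word),
             sprintf("mu: %.17g", fit$hp$mu),
             sprintf("sweeps: %d", fit$state$sweeps),
             sprintf("burn_in: %d", fit$state$burn_in),
             sprintf("seed: %d", fit$state$rng_seed))
  }
  writeLines(man, file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' @rdname write_biolda_model
#' @export
read_biolda_model <- function(dir) {
  rm_ <- function(f) {
    m <- as.matrix(read.delim(file.path(dir, f), row.names = 1,
                              check.names = FALSE))
    m
  }
  structure(list(theta = rm_("theta.tsv"), phi = rm_("phi.tsv"),
                 psi = rm_("psi.tsv")),
            class = "biolda_model")
}
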