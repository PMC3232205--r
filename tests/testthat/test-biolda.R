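test_that("dictionary tagging is case-insensitive, longest-match, non-overlapping", {
  dict <- c("rosiglitazone" = "DB00412",
            "myocardial infarction" = "C0027051",
            "infarction" = "C9999999")
  expect_equal(tag_bioterms(c("Rosiglitazone", "reduces", "glucose"), dict),
               "DB00412")
  hit <- tag_bioterms(c("acute", "Myocardial", "Infarction", "risk"), dict)
  expect_equal(hit, "C0027051")  # 2-word term wins over its suffix
  expect_equal(tag_bioterms(c("no", "match", "here"), dict), character(0))
})

test_that("corpus construction applies stopword and frequency filters", {
  rec <- data.frame(
    tokens = c("ppar gamma receptor binds drug", "insulin glucose uptake pathway db"),
    bioterms = c("BT1", "BT2"), journal = c("J1", "J2"),
    stringsAsFactors = FALSE)
  corpus <- build_corpus(rec)
  expect_equal(length(corpus$vocabulary), 10)
  expect_equal(length(corpus$documents), 2)

  once <- build_corpus(data.frame(tokens = c("alpha alpha beta", "alpha gamma"),
                                  bioterms = c("BT1", "BT1"),
                                  journal = c("J1", "J1")),
                       min_word_count = 2)
  expect_equal(once$vocabulary, "alpha")  # beta and gamma occur once

  expect_error(build_corpus(data.frame(tokens = "the of and",
                                       bioterms = "BT1", journal = "J1"),
                            stopwords = c("the", "of", "and")),
               class = "as_config_error")
})

test_that("documents with no tagged bio-terms get the background term", {
  rec <- data.frame(tokens = c("alpha beta", "gamma delta"),
                    bioterms = c("BT1", ""), journal = c("J1", "J1"),
                    stringsAsFactors = FALSE)
  corpus <- build_corpus(rec)
  expect_true("__BG__" %in% corpus$bioterms)
  expect_true(all(lengths(lapply(corpus$documents, `[[`, "bioterms")) >= 1))
})

test_that("corpus records round-trip through the record file format", {
  gen <- generate_corpus(n_topics = 2, n_bioterms = 4, vocab_size = 20,
                         n_docs = 6, doc_len = 8, seed = 3)
  rec <- corpus_to_records(gen$corpus)
  tmp <- withr::local_tempfile()
  write_corpus_records(rec, tmp)
  rec2 <- read_corpus_records(tmp)
  expect_equal(rec2, rec)
})

test_that("count matrices are conserved and re-derivable from assignments", {
  gen <- generate_corpus(n_topics = 3, n_bioterms = 6, vocab_size = 30,
                         n_docs = 20, doc_len = 10, seed = 5)
  hp <- biolda_hyperparameters(3)
  for (sweeps in c(1L, 2L, 7L)) {
    st <- gibbs_sample(gen$corpus, hp, sweeps = sweeps, burn_in = 0L, seed = 9)
    N <- 20 * 10
    expect_equal(sum(st$n_bt), N)
    expect_equal(sum(st$n_tw), N)
    expect_equal(sum(st$n_tj), N)
    re <- rederive_counts(st, gen$corpus, 3)
    expect_equal(unname(st$n_bt), re$n_bt, ignore_attr = TRUE)
    expect_equal(unname(st$n_tw), re$n_tw, ignore_attr = TRUE)
    expect_equal(unname(st$n_tj), re$n_tj, ignore_attr = TRUE)
    expect_true(all(st$n_bt >= 0) && all(st$n_tw >= 0) && all(st$n_tj >= 0))
  }
})

test_that("a single topic degenerates gracefully", {
  gen <- generate_corpus(n_topics = 1, n_bioterms = 3, vocab_size = 10,
                         n_docs = 5, doc_len = 6, seed = 2)
  st <- gibbs_sample(gen$corpus, biolda_hyperparameters(1),
                     sweeps = 3, burn_in = 0, seed = 1)
  expect_true(all(st$z == 1L))
  expect_equal(sum(st$n_bt[, 1]), 30)
})

test_that("sampler configuration errors are caught", {
  gen <- generate_corpus(n_topics = 2, n_bioterms = 3, vocab_size = 10,
                         n_docs = 4, doc_len = 5, seed = 2)
  expect_error(biolda_hyperparameters(0), class = "as_config_error")
  expect_error(biolda_hyperparameters(2, alpha = 0), class = "as_config_error")
  expect_error(gibbs_sample(gen$corpus, biolda_hyperparameters(2),
                            sweeps = 5, burn_in = 5, seed = 1),
               class = "as_config_error")
})

test_that("identical seeds reproduce the sampler state exactly", {
  gen <- generate_corpus(n_topics = 3, n_bioterms = 6, vocab_size = 30,
                         n_docs = 15, doc_len = 12, seed = 8)
  hp <- biolda_hyperparameters(3)
  s1 <- gibbs_sample(gen$corpus, hp, sweeps = 20, burn_in = 5, seed = 123)
  s2 <- gibbs_sample(gen$corpus, hp, sweeps = 20, burn_in = 5, seed = 123)
  expect_identical(s1$z, s2$z)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$n_bt, s2$n_bt)
})

test_that("Gibbs frequencies match the enumerated posterior on a micro corpus", {
  corpus <- structure(list(
    documents = list(list(tokens = c(1L, 2L), bioterms = 1L, journal = 1L)),
    vocabulary = c("wa", "wb"), bioterms = "b1", journals = "j1"),
    class = "biolda_corpus")
  hp <- biolda_hyperparameters(2, alpha = 0.5, beta_word = 0.1, mu = 0.1)
  oracle <- micro_topic_posterior(corpus, hp)

  st <- gibbs_sample(corpus, hp, sweeps = 50000, burn_in = 1000, seed = 42,
                     keep_trace = TRUE)
  tr <- st$trace_z[-seq_len(1000), ]
  emp <- vapply(seq_len(nrow(oracle$grid)), function(r)
    mean(tr[, 1] == oracle$grid[r, 1] & tr[, 2] == oracle$grid[r, 2]),
    numeric(1))
  tv <- 0.5 * sum(abs(emp - oracle$prob))
  expect_lt(tv, 0.01)
})

test_that("distribution estimates are the smoothed posterior means", {
  gen <- generate_corpus(n_topics = 2, n_bioterms = 4, vocab_size = 10,
                         n_docs = 8, doc_len = 5, seed = 4)
  hp <- biolda_hyperparameters(2, alpha = 1, beta_word = 0.01, mu = 0.1)
  st <- gibbs_sample(gen$corpus, hp, sweeps = 5, burn_in = 0, seed = 2)

  # hand-built row: force known counts and check the closed form
  st$n_bt[1, ] <- c(3L, 1L)
  model <- estimate_distributions(st, gen$corpus, hp)
  expect_equal(unname(model$theta[1, ]), c(4 / 6, 2 / 6))

  # a bio-term with zero sampled tokens has a uniform topic row
  st$n_bt[2, ] <- c(0L, 0L)
  model <- estimate_distributions(st, gen$corpus, hp)
  expect_equal(unname(model$theta[2, ]), c(0.5, 0.5))

  expect_equal(unname(rowSums(model$theta)), rep(1, nrow(model$theta)))
  expect_equal(unname(rowSums(model$phi)), rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(rowSums(model$psi)), rep(1, 2), tolerance = 1e-9)
  expect_true(all(model$theta > 0) && all(model$phi > 0) && all(model$psi > 0))
})

test_that("entropy and KL match closed-form evaluations", {
  expect_equal(bioterm_entropy(rep(1 / 7, 7)), log(7), tolerance = 1e-9)
  expect_equal(bioterm_entropy(c(1, 0, 0)), 0)
  # closed forms evaluated by hand: -0.5 log 0.5 - 2 (0.25 log 0.25),
  # 0.7 log 1.4 + 0.3 log 0.6, 0.5 log(5/7) + 0.5 log(5/3), and their sum
  expect_equal(bioterm_entropy(c(0.5, 0.25, 0.25)), 1.0397208, tolerance = 1e-6)

  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(0.7, 0.3), c(0.5, 0.5)), 0.0822829,
               tolerance = 1e-6)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.7, 0.3)), 0.0871767,
               tolerance = 1e-6)
  expect_equal(symmetric_kl(c(0.7, 0.3), c(0.5, 0.5)), 0.1694596,
               tolerance = 1e-6)

  set.seed(6)
  for (k in 1:10) {
    p <- runif(4); p <- p / sum(p)
    q <- runif(4); q <- q / sum(q)
    expect_equal(symmetric_kl(p, q), symmetric_kl(q, p), tolerance = 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)),
               class = "as_contract_error")
  expect_error(bioterm_entropy(c(0.5, 0.6)), class = "as_contract_error")
})

test_that("model archives round-trip bit-exactly", {
  gen <- generate_corpus(n_topics = 2, n_bioterms = 4, vocab_size = 12,
                         n_docs = 10, doc_len = 6, seed = 13)
  fit <- biolda_train(gen$corpus, n_topics = 2, sweeps = 10, burn_in = 2,
                      seed = 5)
  dir <- withr::local_tempdir()
  write_biolda_model(fit, dir)
  model2 <- read_biolda_model(dir)
  expect_identical(model2$theta, fit$model$theta)
  expect_identical(model2$phi, fit$model$phi)
  expect_identical(model2$psi, fit$model$psi)
})
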