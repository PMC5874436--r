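# Document-term matrix: construction, sparsity scan, TF-IDF, empty docs.

two_doc_dtm <- function() {
  build_dtm(list(list(message_id = "d1", tokens = c("a", "b", "a")),
                 list(message_id = "d2", tokens = c("b", "c"))))
}

test_that("counts, vocabulary and sparsity match hand computation", {
  dtm <- two_doc_dtm()
  expect_equal(dtm$vocabulary, c("a", "b", "c"))
  expect_equal(unname(as.matrix(dtm$counts)),
               rbind(c(2, 1, 0), c(0, 1, 1)))
  expect_equal(dtm$sparsity, 2 / 6)
  expect_equal(sum(dtm$counts), 5)
  expect_equal(dtm$doc_freq, c(1, 2, 1))
  one <- build_dtm(list(list(message_id = "d", tokens = "a")))
  expect_equal(dim(one$counts), c(1L, 1L))
  expect_equal(one$sparsity, 0)
  expect_error(build_dtm(list(list(message_id = "d", tokens = character(0)))),
               "empty")
})

test_that("per-term sparsity is the fraction of documents lacking the term", {
  dtm <- two_doc_dtm()
  expect_equal(term_sparsity(dtm, "b"), 0)
  expect_equal(term_sparsity(dtm, "a"), 0.5)
  expect_error(term_sparsity(dtm, "zz"), "not in vocabulary")
  docs200 <- c(list(list(message_id = "r1", tokens = c("common", "rare"))),
               lapply(2:200, function(i) list(message_id = paste0("r", i),
                                              tokens = "common")))
  expect_equal(term_sparsity(build_dtm(docs200), "rare"), 0.995)
})

test_that("the sparsity scan stops at the first candidate meeting the target", {
  # every term in every doc: first candidate keeps all, overall sparsity 0
  docs <- lapply(1:4, function(i) list(message_id = paste0("d", i),
                                       tokens = c("x", "y")))
  sel <- select_vocabulary(build_dtm(docs), run_config())
  expect_equal(sel$threshold, 0.9995)
  expect_equal(sel$dtm$sparsity, 0)
  expect_equal(nrow(sel$scan), 1L)
  # 10 docs: one term in 1 doc (sparsity 0.9), others in >= 9 docs;
  # brute-force enumeration of the scan is the oracle
  docs10 <- lapply(1:10, function(i) {
    toks <- c("u", if (i <= 9) "v", if (i == 1) "rare")
    list(message_id = paste0("d", i), tokens = toks)
  })
  dtm10 <- build_dtm(docs10)
  cfg <- run_config(sparsity_target = 0.25)
  sel10 <- select_vocabulary(dtm10, cfg)
  grid <- seq(0.9995, 0.80, by = -0.00025)
  brute <- function(cand) {
    keep <- which(vapply(dtm10$vocabulary,
                         function(t) term_sparsity(dtm10, t), 1) <= cand + 1e-12)
    M <- as.matrix(dtm10$counts[, keep, drop = FALSE])
    sum(M == 0) / length(M)
  }
  ok <- vapply(grid, function(g) brute(g) <= cfg$sparsity_target, NA)
  expect_equal(sel10$threshold, grid[which(ok)[1]])
  # the rare term (sparsity 0.9) is dropped exactly when candidate < 0.9
  expect_true("rare" %in% sel10$dtm$vocabulary == (sel10$threshold >= 0.9))
  # vocabulary size is non-increasing as the candidate decreases
  expect_true(all(diff(sel10$scan$n_terms) <= 0))
})

test_that("vocabulary selection is order-independent in the documents", {
  sim <- generate_corpus(sim_config(D = 60, V = 30, K_true = 2,
                                    mean_doc_length = 12, seed = 21))
  docs <- preprocess_corpus(sim$corpus, run_config(drug_names = "seroplex"))
  perm <- sample(seq_along(docs))
  a <- select_vocabulary(build_dtm(docs), run_config())
  b <- select_vocabulary(build_dtm(docs[perm]), run_config())
  expect_equal(a$threshold, b$threshold)
  expect_equal(a$dtm$vocabulary, b$dtm$vocabulary)
  expect_equal(a$dtm$sparsity, b$dtm$sparsity)
  # conservation: totals restricted to the kept vocabulary
  keep <- match(a$dtm$vocabulary, build_dtm(docs)$vocabulary)
  expect_equal(sum(a$dtm$counts),
               sum(build_dtm(docs)$counts[, keep]))
})

test_that("TF-IDF follows the length-normalized log2 formula", {
  docs <- list(list(message_id = "d1", tokens = c("q", "q", "x", "y")),
               list(message_id = "d2", tokens = c("x", "y")),
               list(message_id = "d3", tokens = c("x", "y")),
               list(message_id = "d4", tokens = c("x", "y")))
  w <- tfidf_weight(build_dtm(docs))
  # doc_freq("q") = 1, count 2 of row total 4: 0.5 * log2(4) = 1
  expect_equal(w$values["d1", "q"], 1.0)
  # terms present in every document have zero weight
  expect_true(all(as.matrix(w$values)[, c("x", "y")] == 0))
  expect_true(all(as.matrix(w$values) >= 0))
})

test_that("emptied documents are dropped with their ids reported", {
  dtm <- two_doc_dtm()
  no_op <- drop_empty_documents(dtm)
  expect_equal(no_op$removed, character(0))
  expect_equal(no_op$dtm$doc_ids, dtm$doc_ids)
  # force an empty row by restricting to a term absent from one doc
  dtm_a <- build_dtm(list(list(message_id = "d1", tokens = c("a", "a")),
                          list(message_id = "d2", tokens = "b")))
  m2 <- dtm_a$counts[, "a", drop = FALSE]
  forced <- structure(list(doc_ids = dtm_a$doc_ids, vocabulary = "a",
                           counts = m2,
                           doc_freq = Matrix::colSums(m2 > 0),
                           sparsity = 0.5), class = "nonadh_dtm")
  dropped <- drop_empty_documents(forced)
  expect_equal(dropped$removed, "d2")
  expect_equal(dropped$dtm$doc_ids, "d1")
  expect_equal(as.numeric(dropped$dtm$doc_freq), 1)
  expect_error(tfidf_weight(forced), "drop_empty_documents")
  expect_error(lda_map(forced, 2), "drop_empty_documents")
})
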