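# Synthetic forum-corpus generator and gold scoring.

test_that("generation is deterministic per seed and honors D = 0", {
  cfg <- sim_config(D = 25, V = 20, K_true = 2, mean_doc_length = 15,
                    seed = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$gold$theta, b$gold$theta)
  empty <- generate_corpus(sim_config(D = 0))
  expect_equal(nrow(empty$corpus), 0L)
  expect_length(empty$gold$flag, 0L)
  c2 <- generate_corpus(sim_config(D = 25, V = 20, K_true = 2,
                                   mean_doc_length = 15, seed = 6))
  expect_false(identical(a$corpus$text, c2$corpus$text))
})

test_that("every message carries the drug name exactly once, then never again", {
  sim <- generate_corpus(sim_config(D = 40, V = 25, K_true = 2,
                                    mean_doc_length = 18, seed = 8))
  n_drug <- vapply(sim$corpus$text, function(t) {
    length(gregexpr("seroplex", tolower(t), fixed = TRUE)[[1]])
  }, 1L, USE.NAMES = FALSE)
  expect_true(all(n_drug == 1L))
  docs <- preprocess_corpus(sim$corpus, run_config(drug_names = "seroplex"))
  toks <- unlist(lapply(docs, `[[`, "tokens"))
  expect_false(any(grepl("seroplex", toks, fixed = TRUE)))
})

test_that("injected dosage strings are absorbed into the neutral token", {
  sim <- generate_corpus(sim_config(D = 60, V = 25, K_true = 3,
                                    mean_doc_length = 25, seed = 12,
                                    dosage_emission = 0.5))
  has_dose_sym <- vapply(sim$gold$docs,
                         function(d) any(d$tokens == "__DOSE__"), NA)
  expect_gt(sum(has_dose_sym), 0L)
  docs <- preprocess_corpus(sim$corpus, run_config(drug_names = "seroplex"))
  toks <- unlist(lapply(docs, `[[`, "tokens"))
  expect_true("dosemilligrams" %in% toks)
  unigrams <- toks[!grepl("_", toks, fixed = TRUE)]
  expect_false(any(grepl("^\\d", unigrams) & grepl("mg|mcg|ml$", unigrams)))
  # documents whose gold tokens include the dosage symbol contain the token
  with_sym <- which(has_dose_sym)
  got <- vapply(docs[with_sym],
                function(d) "dosemilligrams" %in% d$tokens, NA)
  expect_true(all(got))
})

test_that("gold flags equal thresholded noncompliance topic mass", {
  cfg <- sim_config(D = 50, V = 20, K_true = 4, seed = 3,
                    mean_doc_length = 10, flag_threshold = 0.5)
  sim <- generate_corpus(cfg)
  nct <- cfg$noncompliance_topics
  manual <- apply(sim$gold$theta[, nct, drop = FALSE] >= 0.5, 1, any)
  expect_equal(unname(sim$gold$flag), unname(manual))
  expect_equal(names(sim$gold$flag), sim$corpus$id)
})

test_that("pooled token distribution approaches the planted mixture", {
  sim <- generate_corpus(sim_config(D = 2000, V = 50, K_true = 3,
                                    mean_doc_length = 30, seed = 42))
  lens <- lengths(lapply(sim$gold$docs, `[[`, "tokens"))
  expected <- colSums((lens * sim$gold$theta) %*% sim$gold$phi)
  expected <- expected / sum(expected)
  toks <- unlist(lapply(sim$gold$docs, `[[`, "tokens"))
  emp <- table(factor(toks, levels = colnames(sim$gold$phi)))
  emp <- as.numeric(emp) / sum(emp)
  tv <- 0.5 * sum(abs(emp - expected))
  expect_lt(tv, 0.05)
})

test_that("gold confusion counts are conserved and validated", {
  flag <- c(m1 = TRUE, m2 = FALSE, m3 = TRUE, m4 = FALSE)
  perfect <- gold_confusion(c("m1", "m3"), flag)
  expect_equal(perfect[["fp"]] + perfect[["fn"]], 0)
  none <- gold_confusion(character(0), flag)
  expect_equal(none[["fn"]], 2)
  expect_equal(sum(none), 4)
  expect_equal(sum(gold_confusion(c("m1", "m2"), flag)), 4)
  expect_error(gold_confusion("zz", flag), "absent from gold")
})

test_that("topic matching pairs planted and fitted topics greedily by cosine", {
  phi <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
  colnames(phi) <- c("a", "b", "c")
  mt <- match_topics(phi[2:1, ], phi)
  expect_equal(mt$fitted[mt$reference == 1], 2L)
  expect_equal(mt$fitted[mt$reference == 2], 1L)
  expect_true(all(mt$cosine > 0.999))
  expect_error(match_topics(phi, matrix(1, 1, 1,
                                        dimnames = list(NULL, "zz"))),
               "no shared vocabulary")
})

test_that("planted distributions map onto stem space with mass conserved", {
  sim <- generate_corpus(sim_config(D = 5, V = 20, K_true = 3, seed = 2))
  ref <- planted_phi_stems(sim$gold)
  expect_equal(rowSums(ref), rep(1, 3), tolerance = 1e-12)
  expect_true("dosemilligrams" %in% colnames(ref))
  expect_false("__DOSE__" %in% colnames(ref))
})
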