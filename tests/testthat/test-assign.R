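# Token-topic association, the 25% assignment rule, extraction.

test_that("token-topic association maximizes theta * phi with low-index ties", {
  m1 <- hand_model(1, "a")
  expect_equal(token_topic(m1, 1, "a"), 1L)
  # exact tie across two topics -> lowest index
  tie <- hand_model(2, c("a", "b"))
  tie$phi[] <- 0.5
  expect_equal(token_topic(tie, 1, "a"), 1L)
  # dominance through theta
  dom <- hand_model(2, c("a", "b"), doc_ids = "d1")
  dom$theta[1, ] <- c(0.99, 0.01)
  dom$phi[] <- 0.5
  expect_equal(token_topic(dom, "d1", "b"), 1L)
  expect_error(token_topic(m1, 1, "zz"), "not in vocabulary")
})

test_that("token fractions and threshold sets follow the 25% rule", {
  m <- hand_model(3, c("a", "b", "c"))
  doc <- list(message_id = "x", tokens = c(rep("a", 5), rep("b", 3),
                                           rep("c", 2)))
  asg <- assign_document(m, doc, tau = 0.25)
  expect_equal(asg$token_fractions, c(0.5, 0.3, 0.2))
  expect_equal(asg$assigned, c(1L, 2L))
  m4 <- hand_model(4, c("a", "b", "c", "d"))
  doc4 <- list(message_id = "x", tokens = c(rep("a", 6), rep("b", 6),
                                            rep("c", 6), rep("d", 7)))
  asg4 <- assign_document(m4, doc4, tau = 0.25)
  expect_equal(asg4$token_fractions, c(6, 6, 6, 7) / 25)
  expect_equal(asg4$assigned, 4L)
  # all tokens on one topic
  one <- assign_document(m, list(message_id = "y", tokens = rep("b", 4)))
  expect_equal(one$assigned, 2L)
  expect_equal(one$token_fractions[2], 1)
  # out-of-vocabulary only: empty assignment, zero fractions
  oov <- assign_document(m, list(message_id = "z", tokens = c("qq", "rr")))
  expect_equal(oov$assigned, integer(0))
  expect_equal(oov$token_fractions, c(0, 0, 0))
})

test_that("fraction sums, set-size bound and anti-monotonicity hold on fits", {
  sim <- generate_corpus(sim_config(D = 80, V = 40, K_true = 3,
                                    mean_doc_length = 20, seed = 13))
  dtm <- build_dtm(sim$gold$docs)
  fit <- lda_map(dtm, 3, seed = 13, n_restarts = 1)
  a25 <- assign_corpus(fit, sim$gold$docs, tau = 0.25)
  sums <- rowSums(a25$token_fractions)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  expect_true(all(lengths(a25$assigned) <= floor(1 / 0.25)))
  a40 <- assign_corpus(fit, sim$gold$docs, tau = 0.40)
  for (i in seq_along(a25$assigned)) {
    expect_true(all(a40$assigned[[i]] %in% a25$assigned[[i]]))
  }
})

test_that("unseen documents are folded in with fixed topics", {
  sim <- generate_corpus(sim_config(D = 60, V = 30, K_true = 2,
                                    mean_doc_length = 25, seed = 19))
  fit <- lda_map(build_dtm(sim$gold$docs), 2, seed = 19, n_restarts = 1)
  new_doc <- list(message_id = "unseen",
                  tokens = sim$gold$docs[[1]]$tokens)
  a <- assign_document(fit, new_doc)
  expect_equal(sum(a$token_fractions), 1, tolerance = 1e-9)
  expect_gt(length(a$assigned), 0L)
})

test_that("assignment summaries match hand computation", {
  asg <- structure(list(message_id = c("a", "b", "c"),
                        token_fractions = matrix(0, 3, 2),
                        assigned = list(1L, c(1L, 2L), integer(0)),
                        tau = 0.25),
                   class = "nonadh_assignments")
  st <- assignment_stats(asg)
  expect_equal(st$topic_counts, c(2L, 1L))
  expect_equal(st$topic_proportions, c(2 / 3, 1 / 3))
  expect_equal(st$n_unassigned, 1L)
  expect_equal(st$mean_topics_per_message, 1.5)
  expect_equal(st$median_topics_per_message, 1.5)
  none <- structure(list(message_id = c("a", "b"),
                         token_fractions = matrix(0, 2, 2),
                         assigned = list(integer(0), integer(0)),
                         tau = 0.25),
                    class = "nonadh_assignments")
  st0 <- assignment_stats(none)
  expect_equal(st0$n_unassigned, 2L)
  expect_true(is.na(st0$mean_topics_per_message))
  expect_true(is.na(st0$median_topics_per_message))
})

test_that("flag extraction collects labeled topics and their intersection", {
  asg <- structure(list(message_id = c("m1", "m2", "m3"),
                        token_fractions = matrix(0, 3, 11),
                        assigned = list(4L, 11L, c(4L, 11L)),
                        tau = 0.25),
                   class = "nonadh_assignments")
  labels <- c(`4` = "treatment_cessation", `11` = "dosage_variation")
  ex <- extract_flagged(asg, labels)
  expect_setequal(ex$by_label$treatment_cessation, c("m1", "m3"))
  expect_setequal(ex$by_label$dosage_variation, c("m2", "m3"))
  expect_equal(ex$intersection, "m3")
  expect_setequal(ex$flagged, c("m1", "m2", "m3"))
  expect_warning(
    ex0 <- extract_flagged(asg, c(`2` = "other"),
                           noncompliance_labels = "dosage_variation"),
    "no topic")
  expect_equal(ex0$by_label$dosage_variation, character(0))
  expect_equal(length(ex0$flagged), 0L)
})
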