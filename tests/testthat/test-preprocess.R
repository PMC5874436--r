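# Preprocessing: dosage standardization, tokenization, filtering, n-grams.

test_that("dosage mentions collapse to the neutral token", {
  expect_equal(standardize_dosage("10 mg"), "dosemilligrams")
  expect_equal(standardize_dosage("je prends 2,5mg le soir"),
               "je prends dosemilligrams le soir")
  expect_equal(standardize_dosage("j'ai pris 3 comprimés"),
               "j'ai pris 3 comprimés")
  expect_equal(standardize_dosage("de 20 MG à 0.5 milligrammes"),
               "de dosemilligrams à dosemilligrams")
  expect_equal(standardize_dosage("dose de 1 g puis 500 mcg"),
               "dose de dosemilligrams puis dosemilligrams")
  # numbers embedded in words are not dosage mentions
  expect_equal(standardize_dosage("b12 mg"), "b12 mg")
  expect_equal(standardize_dosage("w010 mg reste w010"),
               "w010 mg reste w010")
})

test_that("dosage standardization is idempotent and total", {
  x <- c("10 mg et 2,5 mg", "", "rien ici", "15mg!")
  once <- standardize_dosage(x)
  expect_equal(standardize_dosage(once), once)
})

test_that("tokenization lowercases, strips punctuation, splits elisions", {
  expect_equal(tokenize_text("Bonjour, ça VA!"), c("bonjour", "ça", "va"))
  expect_equal(tokenize_text(""), character(0))
  expect_equal(tokenize_text("...!?"), character(0))
  expect_equal(tokenize_text("l'arrêt du traitement"),
               c("l", "arrêt", "du", "traitement"))
  expect_equal(tokenize_text("Effets  secondaires ?"),
               c("effets", "secondaires"))
})

test_that("stopword and drug-name removal are exact order-preserving filters", {
  expect_equal(remove_stopwords(c("je", "prends", "dosemilligrams"), "je"),
               c("prends", "dosemilligrams"))
  expect_equal(remove_stopwords(character(0), c("je")), character(0))
  toks <- c("prends", "dosemilligrams")
  expect_equal(remove_stopwords(toks, c("autre")), toks)
  expect_equal(remove_drug_mentions(c("seroplex", "me", "aide"), "seroplex"),
               c("me", "aide"))
  expect_equal(remove_drug_mentions("abilify", c("abilify", "aripiprazole")),
               character(0))
  # exact-match contract: misspellings are retained
  expect_equal(remove_drug_mentions("seroplexe", "seroplex"), "seroplexe")
})

test_that("n-gram construction appends adjacent bigrams", {
  expect_equal(build_ngrams(c("a", "b", "c")),
               c("a", "b", "c", "a_b", "b_c"))
  expect_equal(build_ngrams("a"), "a")
  expect_equal(build_ngrams(character(0)), character(0))
  expect_equal(build_ngrams(c("a", "b"), orders = 1L), c("a", "b"))
  expect_equal(build_ngrams(c("a", "b"), orders = 2L), "a_b")
})

test_that("full message preprocessing satisfies its contracts", {
  cfg <- toy_config()
  out <- preprocess_message("Je prends du Seroplex 10 mg.", cfg, id = "m1")
  expect_equal(out$message_id, "m1")
  expect_true("dosemilligrams" %in% out$tokens)
  expect_false(any(grepl("seroplex", out$tokens, fixed = TRUE)))
  expect_false(any(out$tokens %in% cfg$stopwords))
  # message of only stopwords
  empty <- preprocess_message("Je ne le la un une.", cfg, id = "m2")
  expect_equal(empty$tokens, character(0))
  # unigram/bigram counting: n unigrams then n-1 bigrams
  cfg1 <- toy_config(ngram_orders = 1L)
  uni <- preprocess_message("fatigue insomnie angoisse nausée.", cfg1,
                            id = "m3")$tokens
  both <- preprocess_message("fatigue insomnie angoisse nausée.", cfg,
                             id = "m3")$tokens
  expect_equal(length(both), 2L * length(uni) - 1L)
  expect_equal(both[seq_along(uni)], uni)
})

test_that("cleaning filters are idempotent on their own output", {
  cfg <- toy_config()
  raw <- "J'ai arrêté le Seroplex 10 mg, trop d'effets secondaires !"
  toks <- tokenize_text(standardize_dosage(raw))
  toks <- remove_stopwords(toks, cfg$stopwords)
  toks <- remove_drug_mentions(toks, cfg$drug_names)
  again <- remove_drug_mentions(remove_stopwords(toks, cfg$stopwords),
                                cfg$drug_names)
  expect_identical(again, toks)
  # re-tokenizing the joined cleaned tokens is also stable
  expect_identical(tokenize_text(paste(toks, collapse = " ")), toks)
})

test_that("corpus-level preprocessing matches per-message preprocessing", {
  cfg <- toy_config()
  corpus <- read_corpus(toy_corpus_path())
  bulk <- preprocess_corpus(corpus, cfg)
  for (i in seq_len(nrow(corpus))) {
    single <- preprocess_message(corpus[i, ], cfg)
    expect_identical(bulk[[i]], single)
  }
  expect_identical(preprocess_corpus(corpus, cfg), bulk)
})

test_that("no output token matches the dosage pattern, a drug or a stopword", {
  cfg <- run_config(drug_names = "seroplex")
  sim <- generate_corpus(sim_config(D = 150, V = 50, K_true = 3,
                                    mean_doc_length = 25, seed = 9))
  docs <- preprocess_corpus(sim$corpus, cfg)
  toks <- unlist(lapply(docs, `[[`, "tokens"))
  expect_gt(length(toks), 0L)
  expect_false(any(toks %in% cfg$stopwords))
  expect_false(any(toks == "seroplex"))
  unigrams <- toks[!grepl("_", toks, fixed = TRUE)]
  expect_false(any(grepl("^\\d+([.,]\\d+)?\\s*(mg|g|mcg|ml)$", unigrams)))
})
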