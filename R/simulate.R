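# Synthetic forum-corpus generator: documents drawn from the LDA generative
# process with planted noncompliance topics, rendered as short noisy
# French-like posts (drug-name mention, stopwords, punctuation, literal
# dosage strings). Stands in for undeposited real forum corpora.

.dose_symbol <- "__DOSE__"

.cessation_seeds <- c("arret", "stop", "abandon", "cess", "suspend",
                      "interromp", "quitt")
.dosage_seeds <- c("dos", "augment", "diminu", "baiss", "reduit", "demi")

.dose_strings <- c("10 mg", "5 mg", "2,5 mg", "15mg", "20 mg", "0,5 mg",
                   "7,5 mg", "1 g")

#' Configuration of the synthetic corpus generator
#'
#' The defaults emulate the kind of corpus the pipeline targets: a few
#' hundred short, noisy French-like posts, each mentioning the drug once,
#' mixing a handful of topics per post, with two planted noncompliance
#' topics (treatment cessation and dosage variation, the latter emitting
#' literal dosage strings such as "10 mg").
#'
#' @param D number of documents (>= 0).
#' @param V content vocabulary size (synthetic stems `w001`, `w002`, ...).
#' @param K_true number of planted topics.
#' @param alpha_doc Dirichlet concentration of document-topic draws; small
#'   values give posts dominated by one or two topics.
#' @param topic_peakedness Dirichlet concentration of planted topic-term
#'   draws; small values give sharply peaked topics.
#' @param mean_doc_length Poisson mean post length in tokens (minimum 1).
#' @param noncompliance_topics named integer vector giving the planted topic
#'   index of the `"treatment_cessation"` and `"dosage_variation"` topics
#'   (subset of `1..K_true`); set to `NULL` for none.
#' @param seed_mass fraction of a noncompliance topic's probability mass
#'   placed on its curated seed vocabulary.
#' @param dosage_emission fraction of the dosage topic's seed mass emitted as
#'   a literal dosage string.
#' @param drug_name drug name inserted exactly once per post.
#' @param stopword_rate per-token probability of inserting a stopword.
#' @param flag_threshold topic-mass level at or above which a document is a
#'   gold noncompliance document.
#' @param seed integer seed.
#' @return list of class `"nonadh_simconfig"`.
#' @export
sim_config <- function(D = 500L, V = 200L, K_true = 5L,
                       alpha_doc = 0.3, topic_peakedness = 0.05,
                       mean_doc_length = 60,
                       noncompliance_topics = c(treatment_cessation = 1L,
                                                dosage_variation = 2L),
                       seed_mass = 0.6, dosage_emission = 0.25,
                       drug_name = "seroplex", stopword_rate = 0.3,
                       flag_threshold = 0.5, seed = 1L) {
  stopifnot(D >= 0L, V >= 1L, K_true >= 1L,
            alpha_doc > 0, topic_peakedness > 0, mean_doc_length > 0,
            seed_mass >= 0, seed_mass <= 1,
            dosage_emission >= 0, dosage_emission <= 1,
            stopword_rate >= 0, stopword_rate <= 1,
            flag_threshold >= 0, flag_threshold <= 1)
  if (!is.null(noncompliance_topics)) {
    stopifnot(all(noncompliance_topics >= 1L),
              all(noncompliance_topics <= K_true),
              all(names(noncompliance_topics) %in%
                    c("treatment_cessation", "dosage_variation")))
  }
  structure(list(D = as.integer(D), V = as.integer(V),
                 K_true = as.integer(K_true),
                 alpha_doc = alpha_doc, topic_peakedness = topic_peakedness,
                 mean_doc_length = mean_doc_length,
                 noncompliance_topics = noncompliance_topics,
                 seed_mass = seed_mass, dosage_emission = dosage_emission,
                 drug_name = drug_name, stopword_rate = stopword_rate,
                 flag_threshold = flag_threshold, seed = as.integer(seed)),
            class = "nonadh_simconfig")
}

.planted_phi <- function(cfg) {
  content <- sprintf("w%03d", seq_len(cfg$V))
  vocab <- c(content, .cessation_seeds, .dosage_seeds, .dose_symbol)
  K <- cfg$K_true
  phi <- matrix(0, nrow = K, ncol = length(vocab),
                dimnames = list(NULL, vocab))
  base <- .rdirichlet_rows(K, cfg$V, cfg$topic_peakedness)
  phi[, seq_len(cfg$V)] <- base
  nct <- cfg$noncompliance_topics
  if (!is.null(nct) && "treatment_cessation" %in% names(nct)) {
    k <- nct[["treatment_cessation"]]
    w <- as.vector(.rdirichlet_rows(1, length(.cessation_seeds), 1))
    phi[k, seq_len(cfg$V)] <- base[k, ] * (1 - cfg$seed_mass)
    phi[k, .cessation_seeds] <- cfg$seed_mass * w
  }
  if (!is.null(nct) && "dosage_variation" %in% names(nct)) {
    k <- nct[["dosage_variation"]]
    w <- as.vector(.rdirichlet_rows(1, length(.dosage_seeds), 1))
    phi[k, seq_len(cfg$V)] <- base[k, ] * (1 - cfg$seed_mass)
    phi[k, .dosage_seeds] <- cfg$seed_mass * (1 - cfg$dosage_emission) * w
    phi[k, .dose_symbol] <- cfg$seed_mass * cfg$dosage_emission
  }
  phi / rowSums(phi)
}

.render_message <- function(tokens, drug_name, stopword_rate, stopwords) {
  words <- tokens
  is_dose <- words == .dose_symbol
  if (any(is_dose)) {
    words[is_dose] <- sample(.dose_strings, sum(is_dose), replace = TRUE)
  }
  if (stopword_rate > 0 && length(stopwords) > 0L) {
    ins <- stats::runif(length(words)) < stopword_rate
    if (any(ins)) {
      sw <- sample(stopwords, sum(ins), replace = TRUE)
      merged <- character(0)
      j <- 1L
      for (i in seq_along(words)) {
        if (ins[i]) { merged <- c(merged, sw[j]); j <- j + 1L }
        merged <- c(merged, words[i])
      }
      words <- merged
    }
  }
  pos <- sample.int(length(words) + 1L, 1L)
  words <- append(words, drug_name, after = pos - 1L)
  # sentence punctuation: commas and full stops at random positions
  n <- length(words)
  punct <- sample(c("", "", "", "", ",", "."), n, replace = TRUE)
  text <- paste0(words, punct, collapse = " ")
  paste0(toupper(substring(text, 1, 1)), substring(text, 2), ".")
}

#' Generate a synthetic forum corpus with gold labels
#'
#' Draws planted topic-term distributions from a Dirichlet over a synthetic
#' content vocabulary (with curated French-like seed stems for the planted
#' noncompliance topics), then documents from the LDA generative process:
#' topic weights from a Dirichlet, Poisson lengths, topic-then-word token
#' sampling. Each document is rendered as forum-post text with the drug name
#' inserted exactly once, stopwords interleaved at the configured rate,
#' sentence punctuation, and literal dosage strings (e.g. "10 mg") for
#' dosage-symbol tokens. A document is a gold noncompliance document when
#' its generative mass on any noncompliance topic reaches `flag_threshold`.
#'
#' @param cfg a [sim_config()] object.
#' @param stopwords stopword pool for noise insertion (default: the bundled
#'   French list).
#' @return list with `corpus` (message data frame: `id`, `date`, `forum`,
#'   `text`) and `gold` (list with planted `phi` over the symbol vocabulary,
#'   `theta`, token-level `docs`, per-document logical `flag` named by
#'   message id, `dominant_topic`, `noncompliance_topics`, `vocabulary`,
#'   and `config`).
#' @export
generate_corpus <- function(cfg = sim_config(),
                            stopwords = default_stopwords()) {
  stopifnot(inherits(cfg, "nonadh_simconfig"))
  forums <- c("doctissimo", "atoute", "sante-medecine")
  if (cfg$D == 0L) {
    empty <- data.frame(id = character(0), date = character(0),
                        forum = character(0), text = character(0))
    return(list(corpus = empty,
                gold = list(phi = .planted_phi_empty(cfg), theta = NULL,
                            docs = list(), flag = logical(0),
                            dominant_topic = integer(0),
                            noncompliance_topics = cfg$noncompliance_topics,
                            vocabulary = NULL, config = cfg)))
  }
  .with_seed(cfg$seed, {
    phi <- .planted_phi(cfg)
    vocab <- colnames(phi)
    theta <- .rdirichlet_rows(cfg$D, cfg$K_true, cfg$alpha_doc)
    ids <- sprintf("msg%05d", seq_len(cfg$D))
    dates <- format(as.Date("2004-01-01") +
                      sample.int(3652L, cfg$D, replace = TRUE) - 1L,
                    "%Y-%m-%d")
    forum <- sample(forums, cfg$D, replace = TRUE)
    docs <- vector("list", cfg$D)
    text <- character(cfg$D)
    for (d in seq_len(cfg$D)) {
      len <- max(1L, stats::rpois(1L, cfg$mean_doc_length))
      z <- sample.int(cfg$K_true, len, replace = TRUE, prob = theta[d, ])
      toks <- character(len)
      for (k in unique(z)) {
        idx <- which(z == k)
        toks[idx] <- sample(vocab, length(idx), replace = TRUE,
                            prob = phi[k, ])
      }
      docs[[d]] <- list(message_id = ids[d], tokens = toks)
      text[d] <- .render_message(toks, cfg$drug_name, cfg$stopword_rate,
                                 stopwords)
    }
    nct <- cfg$noncompliance_topics
    flag <- if (is.null(nct)) rep(FALSE, cfg$D) else {
      apply(theta[, nct, drop = FALSE], 1L,
            function(r) any(r >= cfg$flag_threshold))
    }
    names(flag) <- ids
    rownames(theta) <- ids
    list(corpus = data.frame(id = ids, date = dates, forum = forum,
                             text = text, stringsAsFactors = FALSE),
         gold = list(phi = phi, theta = theta, docs = docs, flag = flag,
                     dominant_topic = max.col(theta, ties.method = "first"),
                     noncompliance_topics = nct,
                     vocabulary = vocab, config = cfg))
  })
}

.planted_phi_empty <- function(cfg) {
  .with_seed(cfg$seed, .planted_phi(cfg))
}

#' Map a planted topic-term matrix to preprocessed-token space
#'
#' The generator's symbol vocabulary consists of surface words plus the
#' dosage symbol; after preprocessing, surface words become French stems and
#' dosage strings become the literal token `"dosemilligrams"`. This maps the
#' planted distributions accordingly (columns with identical stems are
#' summed), enabling comparison with distributions fitted on preprocessed
#' text.
#'
#' @param gold the `gold` component of [generate_corpus()].
#' @return matrix with stem-space column names.
#' @export
planted_phi_stems <- function(gold) {
  vocab <- colnames(gold$phi)
  stems <- ifelse(vocab == .dose_symbol, "dosemilligrams", stem_tokens(vocab))
  agg <- t(rowsum(t(gold$phi), group = stems))
  agg
}

#' Greedy cosine matching of fitted topics to reference topics
#'
#' For each reference topic (in decreasing order of best available cosine),
#' greedily picks the unmatched fitted topic with the highest cosine
#' similarity, computed over the shared vocabulary columns.
#'
#' @param fitted_phi fitted topic-term matrix with term column names.
#' @param reference_phi reference (e.g. planted) topic-term matrix with term
#'   column names.
#' @return data frame with columns `reference`, `fitted`, `cosine`.
#' @export
match_topics <- function(fitted_phi, reference_phi) {
  shared <- intersect(colnames(fitted_phi), colnames(reference_phi))
  if (length(shared) == 0L) stop("no shared vocabulary between topic matrices")
  A <- reference_phi[, shared, drop = FALSE]
  B <- fitted_phi[, shared, drop = FALSE]
  An <- A / sqrt(pmax(rowSums(A^2), 1e-300))
  Bn <- B / sqrt(pmax(rowSums(B^2), 1e-300))
  cos <- An %*% t(Bn)
  nr <- nrow(A); nf <- nrow(B)
  res <- data.frame(reference = integer(0), fitted = integer(0),
                    cosine = numeric(0))
  free_r <- rep(TRUE, nr); free_f <- rep(TRUE, nf)
  for (step in seq_len(min(nr, nf))) {
    sub <- cos
    sub[!free_r, ] <- -Inf
    sub[, !free_f] <- -Inf
    ij <- arrayInd(which.max(sub), dim(sub))
    res <- rbind(res, data.frame(reference = ij[1L], fitted = ij[2L],
                                 cosine = cos[ij[1L], ij[2L]]))
    free_r[ij[1L]] <- FALSE
    free_f[ij[2L]] <- FALSE
  }
  res[order(res$reference), ]
}

#' Confusion counts of pipeline flags against gold flags
#'
#' @param flagged_ids message ids flagged by the pipeline.
#' @param gold_flag named logical vector of gold noncompliance flags (names
#'   are message ids; the id universe).
#' @return named vector with `tp`, `fp`, `fn`, `tn`.
#' @export
gold_confusion <- function(flagged_ids, gold_flag) {
  ids <- names(gold_flag)
  if (is.null(ids)) stop("`gold_flag` must be named by message id")
  unknown <- setdiff(flagged_ids, ids)
  if (length(unknown) > 0L) {
    stop("flagged id(s) absent from gold: ", paste(utils::head(unknown, 3),
                                                   collapse = ", "))
  }
  pred <- ids %in% flagged_ids
  c(tp = sum(pred & gold_flag), fp = sum(pred & !gold_flag),
    fn = sum(!pred & gold_flag), tn = sum(!pred & !gold_flag))
}

#' Run the full pipeline on a synthetic corpus and score it against gold
#'
#' End-to-end benchmark: generates a corpus, preprocesses the text, builds
#' the document-term matrix, selects the vocabulary by the sparsity scan,
#' drops emptied documents, selects the number of topics by log Bayes
#' factor, assigns messages by the token-fraction rule, labels the fitted
#' topics by greedy cosine matching against the planted noncompliance
#' topics (in stem space), extracts the flagged messages and scores them
#' against the gold flags.
#'
#' @param cfg a [sim_config()] object.
#' @param config a [run_config()]; its `drug_names` are extended with the
#'   simulated drug name.
#' @return list with the fitted `selection`, `assignments`, `labels`,
#'   `extraction`, `confusion`, `recall` and `precision` (percentages on the
#'   gold flags), assignment `stats`, and the generated `corpus`/`gold`.
#' @export
synthetic_benchmark <- function(cfg = sim_config(), config = run_config()) {
  config$drug_names <- unique(c(config$drug_names, cfg$drug_name))
  sim <- generate_corpus(cfg, stopwords = config$stopwords)
  docs <- preprocess_corpus(sim$corpus, config)
  dtm <- build_dtm(docs)
  sel_v <- select_vocabulary(dtm, config)
  dropped <- drop_empty_documents(sel_v$dtm)
  x <- if (config$weighting == "tfidf") tfidf_weight(dropped$dtm)
       else dropped$dtm
  selection <- select_num_topics(x, config)
  model <- selection$model
  assignments <- assign_corpus(model, docs,
                               tau = config$association_threshold)
  # Label every fitted topic by its closest planted topic (cosine in stem
  # space), mirroring how a human labeler reads each estimated topic; fitted
  # topics whose closest planted topic is a noncompliance topic inherit its
  # label, so splits of a planted topic are all labeled.
  ref <- planted_phi_stems(sim$gold)
  nct <- cfg$noncompliance_topics
  shared <- intersect(colnames(model$phi), colnames(ref))
  A <- ref[, shared, drop = FALSE]
  B <- model$phi[, shared, drop = FALSE]
  An <- A / sqrt(pmax(rowSums(A^2), 1e-300))
  Bn <- B / sqrt(pmax(rowSums(B^2), 1e-300))
  closest <- max.col(t(An %*% t(Bn)), ties.method = "first")
  labels <- character(0)
  for (j in seq_len(model$K)) {
    hit <- which(nct == closest[j])
    if (length(hit) == 1L) labels[as.character(j)] <- names(nct)[hit]
  }
  extraction <- extract_flagged(assignments, labels,
                                noncompliance_labels = unique(names(nct)))
  conf <- gold_confusion(extraction$flagged, sim$gold$flag)
  list(selection = selection,
       assignments = assignments,
       labels = labels,
       extraction = extraction,
       confusion = conf,
       recall = recall_pct(conf[["tp"]], conf[["fn"]]),
       precision = precision_pct(conf[["tp"]],
                                 conf[["tp"]] + conf[["fp"]]),
       stats = assignment_stats(assignments),
       removed_docs = dropped$removed,
       sparsity_threshold = sel_v$threshold,
       dtm_sparsity = dropped$dtm$sparsity,
       n_terms = length(dropped$dtm$vocabulary),
       corpus = sim$corpus,
       gold = sim$gold)
}
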