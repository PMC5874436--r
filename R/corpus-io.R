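# Corpus, lexicon and configuration I/O, plus result writers.

.required_fields <- c("id", "date", "forum", "text")

.check_corpus_df <- function(df, allow_empty_text) {
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop("duplicate message id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!allow_empty_text) {
    bad <- which(is.na(df$text) | !nzchar(trimws(df$text)))
    if (length(bad) > 0L) {
      stop("empty `text` in record(s) ", paste(bad, collapse = ", "),
           " (set allow_empty_text = TRUE to accept)")
    }
  }
  df
}

#' Read a forum-post corpus
#'
#' Reads a corpus of forum messages from a JSON-lines file (one object per
#' message) or a CSV file (comma-separated, quoted, header required). Each
#' record must carry the fields `id`, `date`, `forum` and `text`. Messages are
#' returned in file order.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @param allow_empty_text accept records with empty text (default: reject).
#' @return data frame with character columns `id`, `date`, `forum`, `text`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        allow_empty_text = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        stop("line ", i, ": invalid JSON (", conditionMessage(e), ")")
                      })
      missing <- setdiff(.required_fields, names(rec))
      if (length(missing) > 0L) {
        stop("line ", i, ": missing required field(s): ",
             paste(missing, collapse = ", "))
      }
      recs[[i]] <- lapply(rec[.required_fields], function(v) as.character(v)[1L])
    }
    df <- do.call(rbind.data.frame,
                  c(recs, list(stringsAsFactors = FALSE)))
    if (length(recs) == 0L) {
      df <- data.frame(id = character(0), date = character(0),
                       forum = character(0), text = character(0))
    }
    names(df) <- .required_fields
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8", check.names = FALSE)
    missing <- setdiff(.required_fields, names(df))
    if (length(missing) > 0L) {
      stop("CSV header: missing required field(s): ",
           paste(missing, collapse = ", "))
    }
    df <- df[, .required_fields]
  }
  rownames(df) <- NULL
  .check_corpus_df(df, allow_empty_text)
}

#' Write a forum-post corpus
#'
#' Inverse of [read_corpus()]; the round trip is lossless for all fields.
#'
#' @param corpus data frame with columns `id`, `date`, `forum`, `text`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(all(.required_fields %in% names(corpus)))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      writeLines(jsonlite::toJSON(as.list(corpus[i, .required_fields]),
                                  auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(corpus[, .required_fields], path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a plain-text lexicon
#'
#' One entry per line, UTF-8; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of entries.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Default French stopword list
#'
#' The stopword lexicon shipped with the package (a standard French list of
#' function words). Fully overridable via [run_config()].
#'
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_fr.txt", package = "nonadh")
  if (!nzchar(path)) stop("bundled stopword list not found")
  read_lexicon(path)
}

#' Build a run configuration
#'
#' Central container for every tunable of the pipeline. Defaults follow the
#' package's standard protocol: vocabulary selected by a per-term sparsity
#' scan from 0.9995 down to 0.80 in steps of 0.00025 targeting an overall
#' matrix sparsity of 0.97, topic count chosen over `K_grid` by log Bayes
#' factor, messages associated to a topic when at least 25% of their
#' in-vocabulary tokens are assigned to it, topics summarized by their first
#' 15 terms, and 20% review sampling for recall estimation.
#'
#' @param drug_names character vector of drug names to strip (brand and
#'   active-ingredient spellings).
#' @param stopwords character vector of stopwords; `NULL` for the bundled
#'   French list.
#' @param dosage_units unit spellings for [standardize_dosage()].
#' @param sparsity_target overall-sparsity target of the reduced matrix.
#' @param sparsity_scan named numeric vector `c(start, stop, step)` of the
#'   descending per-term sparsity scan.
#' @param association_threshold minimum token fraction tau for message-topic
#'   association.
#' @param K_grid integer vector of candidate topic counts.
#' @param top_n_terms number of top terms used to summarize a topic.
#' @param review_fraction fraction of messages sampled for manual review.
#' @param seed integer seed used by every randomized operation.
#' @param weighting `"counts"` or `"tfidf"` input for the topic model.
#' @param ngram_orders subset of `c(1, 2)`.
#' @param alpha_theta,alpha_phi symmetric Dirichlet hyperparameters (> 1).
#' @param tol,max_iter,n_restarts EM convergence controls.
#' @return a list of class `"nonadh_config"`.
#' @export
run_config <- function(drug_names = character(0),
                       stopwords = NULL,
                       dosage_units = default_dosage_units(),
                       sparsity_target = 0.97,
                       sparsity_scan = c(start = 0.9995, stop = 0.80,
                                         step = 0.00025),
                       association_threshold = 0.25,
                       K_grid = 1:8,
                       top_n_terms = 15L,
                       review_fraction = 0.20,
                       seed = 1L,
                       weighting = c("counts", "tfidf"),
                       ngram_orders = c(1L, 2L),
                       alpha_theta = 1.1,
                       alpha_phi = 1.1,
                       tol = 1e-6,
                       max_iter = 200L,
                       n_restarts = 3L) {
  weighting <- match.arg(weighting)
  if (is.null(stopwords)) stopwords <- default_stopwords()
  stopifnot(
    association_threshold > 0, association_threshold <= 1,
    sparsity_target > 0, sparsity_target < 1,
    length(K_grid) >= 1L, all(K_grid >= 1L),
    top_n_terms >= 1L,
    review_fraction > 0, review_fraction <= 1,
    alpha_theta > 1, alpha_phi > 1
  )
  structure(list(
    drug_names = as.character(drug_names),
    stopwords = as.character(stopwords),
    dosage_units = dosage_units,
    sparsity_target = sparsity_target,
    sparsity_scan = sparsity_scan,
    association_threshold = association_threshold,
    K_grid = as.integer(K_grid),
    top_n_terms = as.integer(top_n_terms),
    review_fraction = review_fraction,
    seed = as.integer(seed),
    weighting = weighting,
    ngram_orders = as.integer(ngram_orders),
    alpha_theta = alpha_theta,
    alpha_phi = alpha_phi,
    tol = tol,
    max_iter = as.integer(max_iter),
    n_restarts = as.integer(n_restarts)
  ), class = "nonadh_config")
}

#' Read a YAML run configuration
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()].
#' `stopword_path` and `drug_path` entries are resolved through
#' [read_lexicon()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file (e.g. from CLI flags).
#' @return a `"nonadh_config"` list.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$stopword_path)) {
    cfg$stopwords <- read_lexicon(file.path(dirname(path), cfg$stopword_path))
    cfg$stopword_path <- NULL
  }
  if (!is.null(cfg$drug_path)) {
    cfg$drug_names <- c(cfg$drug_names,
                        read_lexicon(file.path(dirname(path), cfg$drug_path)))
    cfg$drug_path <- NULL
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, cfg)
}

#' Write topic-model reports
#'
#' Writes three artifacts under `dir`: `topic_terms.tsv` (topic id, rank,
#' term, probability; every term of every topic, ranked by probability),
#' `doc_topics.tsv` (message id, per-topic token fraction, assigned-topic set
#' joined with `;`, empty string when unassigned), and `summary.json` (number
#' of topics, approximate log marginal likelihood, configuration echo).
#' TSVs are tab-separated with `.` as decimal mark.
#'
#' @param model a fitted [lda_map()] model.
#' @param assignments assignment table from [assign_corpus()].
#' @param dir output directory (created if needed).
#' @param config optional `"nonadh_config"` echoed into the JSON summary.
#' @return invisibly, the paths written.
#' @export
write_topic_report <- function(model, assignments, dir, config = NULL) {
  stopifnot(inherits(model, "lda_map"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  K <- model$K
  V <- length(model$vocabulary)
  tt <- do.call(rbind, lapply(seq_len(K), function(k) {
    ord <- order(-model$phi[k, ], model$vocabulary)
    data.frame(topic = k, rank = seq_len(V),
               term = model$vocabulary[ord],
               probability = model$phi[k, ord])
  }))
  p1 <- file.path(dir, "topic_terms.tsv")
  utils::write.table(tt, p1, sep = "\t", dec = ".", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  frac <- assignments$token_fractions
  dt <- data.frame(message_id = assignments$message_id,
                   stringsAsFactors = FALSE)
  colnames(frac) <- paste0("topic_", seq_len(ncol(frac)))
  dt <- cbind(dt, as.data.frame(frac))
  dt$assigned <- vapply(assignments$assigned,
                        function(s) paste(s, collapse = ";"), character(1))
  p2 <- file.path(dir, "doc_topics.tsv")
  utils::write.table(dt, p2, sep = "\t", dec = ".", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  summ <- list(K = K, log_marginal = model$log_marginal,
               converged = model$converged, seed = model$seed)
  if (!is.null(config)) summ$config <- unclass(config)
  p3 <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(topic_terms = p1, doc_topics = p2, summary = p3))
}

#' Export a document-term matrix to MatrixMarket files
#'
#' Writes `dtm.mtx` plus `vocabulary.txt` and `doc_ids.txt` sidecars.
#'
#' @param dtm a [build_dtm()] object.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
export_dtm <- function(dtm, dir) {
  stopifnot(inherits(dtm, "nonadh_dtm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pm <- file.path(dir, "dtm.mtx")
  Matrix::writeMM(methods::as(dtm$counts, "CsparseMatrix"), pm)
  pv <- file.path(dir, "vocabulary.txt")
  writeLines(dtm$vocabulary, pv, useBytes = TRUE)
  pd <- file.path(dir, "doc_ids.txt")
  writeLines(dtm$doc_ids, pd, useBytes = TRUE)
  invisible(c(mtx = pm, vocabulary = pv, doc_ids = pd))
}
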