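# Document-term matrix construction, sparsity-scan vocabulary selection,
# TF-IDF weighting, empty-document removal.

.new_dtm <- function(counts, doc_ids, vocabulary) {
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(doc_ids, vocabulary)
  doc_freq <- Matrix::colSums(counts > 0)
  nzero <- prod(dim(counts)) - Matrix::nnzero(counts)
  structure(list(
    doc_ids = doc_ids,
    vocabulary = vocabulary,
    counts = counts,
    doc_freq = as.numeric(doc_freq),
    sparsity = as.numeric(nzero) / prod(dim(counts))
  ), class = "nonadh_dtm")
}

#' Build a document-term matrix
#'
#' Rows are documents, columns are terms; entries are occurrence counts. The
#' vocabulary is the sorted set of distinct tokens (byte-order sort, so the
#' result is locale-independent).
#'
#' @param docs list of tokenized documents (elements with `message_id` and
#'   `tokens`), as produced by [preprocess_corpus()].
#' @return an object of class `"nonadh_dtm"` with fields `doc_ids`,
#'   `vocabulary`, `counts` (sparse docs x terms matrix), `doc_freq` and
#'   `sparsity` (fraction of zero cells).
#' @export
build_dtm <- function(docs) {
  stopifnot(is.list(docs), length(docs) >= 1L)
  ids <- vapply(docs, function(d) as.character(d$message_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate message ids in `docs`")
  tok <- lapply(docs, function(d) as.character(d$tokens))
  n_tok <- lengths(tok)
  if (sum(n_tok) == 0L) stop("all documents are empty; nothing to build")
  vocab <- sort(unique(unlist(tok, use.names = FALSE)), method = "radix")
  di <- rep.int(seq_along(tok), n_tok)
  ti <- match(unlist(tok, use.names = FALSE), vocab)
  counts <- Matrix::sparseMatrix(i = di, j = ti, x = 1,
                                 dims = c(length(tok), length(vocab)))
  .new_dtm(counts, ids, vocab)
}

#' @export
print.nonadh_dtm <- function(x, ...) {
  cat(sprintf("Document-term matrix: %d documents x %d terms, sparsity %.4f\n",
              nrow(x$counts), ncol(x$counts), x$sparsity))
  invisible(x)
}

.dtm_subset <- function(dtm, rows = NULL, cols = NULL) {
  counts <- dtm$counts
  ids <- dtm$doc_ids
  vocab <- dtm$vocabulary
  if (!is.null(cols)) {
    counts <- counts[, cols, drop = FALSE]
    vocab <- vocab[cols]
  }
  if (!is.null(rows)) {
    counts <- counts[rows, , drop = FALSE]
    ids <- ids[rows]
  }
  .new_dtm(counts, ids, vocab)
}

#' Per-term sparsity
#'
#' Fraction of documents in which a term does not occur.
#'
#' @param dtm a `"nonadh_dtm"` object.
#' @param term a term present in the vocabulary.
#' @return sparsity fraction in `[0, 1)`.
#' @export
term_sparsity <- function(dtm, term) {
  stopifnot(inherits(dtm, "nonadh_dtm"))
  j <- match(term, dtm$vocabulary)
  if (is.na(j)) stop("term not in vocabulary: ", term)
  1 - dtm$doc_freq[j] / nrow(dtm$counts)
}

#' Select the vocabulary by a descending sparsity scan
#'
#' Scans candidate per-term sparsity thresholds descending from
#' `sparsity_scan["start"]` to `sparsity_scan["stop"]` in steps of
#' `sparsity_scan["step"]`. At each candidate, every term whose per-term
#' sparsity exceeds the candidate is dropped and the overall sparsity of the
#' reduced matrix is computed. The first (largest) candidate at which the
#' overall sparsity is at or below `sparsity_target` is returned together
#' with the reduced matrix; if no candidate achieves the target, the last
#' candidate's matrix is returned with a warning.
#'
#' @param dtm a `"nonadh_dtm"` object.
#' @param config a [run_config()] list (fields `sparsity_scan`,
#'   `sparsity_target`).
#' @return list with `threshold` (the selected candidate), `dtm` (reduced
#'   matrix) and `scan` (data frame of candidate, retained term count and
#'   overall sparsity over the scan up to the stopping point).
#' @export
select_vocabulary <- function(dtm, config = run_config()) {
  stopifnot(inherits(dtm, "nonadh_dtm"))
  sc <- config$sparsity_scan
  grid <- seq(sc[["start"]], sc[["stop"]], by = -abs(sc[["step"]]))
  if (length(grid) == 0L) stop("empty sparsity scan grid")
  D <- nrow(dtm$counts)
  ts <- 1 - dtm$doc_freq / D
  ord <- order(ts)
  ts_sorted <- ts[ord]
  df_cum <- cumsum(dtm$doc_freq[ord])
  # number of terms with per-term sparsity <= candidate, and their total
  # document frequency, via the sorted sparsities
  n_kept <- findInterval(grid + 1e-12, ts_sorted)
  overall <- ifelse(n_kept > 0,
                    1 - df_cum[pmax(n_kept, 1L)] / (D * n_kept),
                    NA_real_)
  scan <- data.frame(candidate = grid, n_terms = n_kept, sparsity = overall)
  hit <- which(!is.na(overall) & overall <= config$sparsity_target)
  if (length(hit) > 0L) {
    stop_at <- hit[1L]
  } else {
    stop_at <- length(grid)
    warning("no scan candidate achieved overall sparsity <= ",
            config$sparsity_target, "; returning the last candidate")
  }
  thr <- grid[stop_at]
  keep <- which(ts <= thr + 1e-12)
  if (length(keep) == 0L) stop("selected threshold removes every term")
  list(threshold = thr,
       dtm = .dtm_subset(dtm, cols = keep),
       scan = scan[seq_len(stop_at), ])
}

#' TF-IDF weighting
#'
#' Weights each cell as term frequency normalized by document length times
#' the base-2 log inverse document frequency:
#' `w[d,t] = counts[d,t] / rowtot[d] * log2(D / doc_freq[t])`. A term present
#' in every document receives weight 0 everywhere.
#'
#' @param dtm a `"nonadh_dtm"` with no all-zero row (run
#'   [drop_empty_documents()] first).
#' @return an object of class `"nonadh_weighted"` with the same shape and a
#'   `values` matrix of nonnegative weights.
#' @export
tfidf_weight <- function(dtm) {
  stopifnot(inherits(dtm, "nonadh_dtm"))
  rowtot <- Matrix::rowSums(dtm$counts)
  if (any(rowtot == 0)) {
    stop("document(s) with zero retained tokens; call drop_empty_documents() first")
  }
  D <- nrow(dtm$counts)
  idf <- log2(D / dtm$doc_freq)
  values <- Matrix::Diagonal(x = 1 / rowtot) %*% dtm$counts %*%
    Matrix::Diagonal(x = idf)
  values <- methods::as(values, "CsparseMatrix")
  dimnames(values) <- dimnames(dtm$counts)
  structure(list(doc_ids = dtm$doc_ids,
                 vocabulary = dtm$vocabulary,
                 values = values),
            class = "nonadh_weighted")
}

#' Drop documents emptied by vocabulary selection
#'
#' Removes rows whose retained-vocabulary token total is zero (typically
#' messages consisting only of very rare, e.g. badly misspelled, terms).
#'
#' @param dtm a `"nonadh_dtm"` object.
#' @return list with `dtm` (reduced matrix) and `removed` (character vector
#'   of removed document ids, for logging).
#' @export
drop_empty_documents <- function(dtm) {
  stopifnot(inherits(dtm, "nonadh_dtm"))
  rowtot <- Matrix::rowSums(dtm$counts)
  empty <- which(rowtot == 0)
  if (length(empty) == 0L) {
    return(list(dtm = dtm, removed = character(0)))
  }
  list(dtm = .dtm_subset(dtm, rows = setdiff(seq_along(rowtot), empty)),
       removed = dtm$doc_ids[empty])
}
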