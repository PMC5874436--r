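# Evaluation arithmetic: precision/recall percentages, Cohen kappa,
# review sampling, corpus noncompliance rate.

# Half-away-from-zero rounding (base round() is half-to-even).
.round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Precision percentage
#'
#' The ratio of correctly classified messages among the messages flagged by a
#' topic, as a percentage rounded half-away-from-zero to one decimal.
#'
#' @param tp number of flagged messages confirmed by manual review.
#' @param flagged_n total number of flagged messages.
#' @return percentage, or `NA` when `flagged_n` is 0.
#' @examples
#' precision_pct(54, 187)
#' @export
precision_pct <- function(tp, flagged_n) {
  stopifnot(tp >= 0, flagged_n >= 0, tp <= flagged_n)
  if (flagged_n == 0) return(NA_real_)
  .round_half_away(100 * tp / flagged_n, 1L)
}

#' Recall percentage
#'
#' `100 * tp / (tp + fn)`, rounded half-away-from-zero to one decimal.
#'
#' @param tp true positives.
#' @param fn false negatives (noncompliance messages found in the review
#'   sample of non-noncompliance topics).
#' @return percentage, or `NA` when `tp + fn` is 0.
#' @export
recall_pct <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) return(NA_real_)
  .round_half_away(100 * tp / (tp + fn), 1L)
}

#' Cohen kappa for a square agreement table
#'
#' Chance-corrected inter-annotator agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the
#' diagonal fraction and expected agreement `p_e` the sum of the products of
#' the row and column marginal proportions. Returns 1 for perfect agreement
#' even when `p_e = 1`.
#'
#' @param tab square matrix of agreement counts (annotator 1 in rows,
#'   annotator 2 in columns); typically 2 x 2.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(matrix(c(40, 10, 5, 45), 2))
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab))
  if (any(tab < 0)) stop("negative counts in agreement table")
  n <- sum(tab)
  if (n == 0) stop("empty agreement table")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) return(if (p_o >= 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Sample messages for manual review
#'
#' Simple random sample without replacement of `ceiling(fraction * n)` ids,
#' seeded and deterministic per seed. The ceiling rule reproduces the
#' conventional review-set sizes for 20% sampling (e.g. 345 of 1723 and 650
#' of 3246).
#'
#' @param message_ids character vector of candidate ids.
#' @param fraction sampling fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return character vector of sampled ids.
#' @export
sample_for_review <- function(message_ids, fraction = 0.20, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(message_ids)
  if (n == 0L) return(character(0))
  size <- min(n, as.integer(ceiling(fraction * n)))
  .with_seed(seed, message_ids[sample.int(n, size)])
}

#' Corpus noncompliance rate
#'
#' Percentage of topic-assigned posts confirmed as noncompliance, rounded
#' half-away-from-zero to two decimals (headline-rate convention).
#'
#' @param confirmed number of confirmed noncompliance messages.
#' @param assigned_total total number of topic-assigned messages.
#' @return percentage, or `NA` when `assigned_total` is 0.
#' @export
noncompliance_rate <- function(confirmed, assigned_total) {
  stopifnot(confirmed >= 0, assigned_total >= 0)
  if (assigned_total == 0) return(NA_real_)
  .round_half_away(100 * confirmed / assigned_total, 2L)
}

#' Read reviewed outcomes
#'
#' CSV with columns `message_id`, `label`, `annotator_id`, `verdict`
#' (logical-like: TRUE/FALSE, 1/0, yes/no). Manual verdicts are external
#' input; the package never infers truth labels.
#'
#' @param path CSV file path.
#' @return data frame with a logical `verdict` column.
#' @export
read_review_outcomes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("message_id", "label", "annotator_id", "verdict")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("review CSV: missing column(s): ", paste(missing, collapse = ", "))
  }
  v <- tolower(trimws(df$verdict))
  df$verdict <- v %in% c("true", "t", "1", "yes", "y")
  df
}

#' Assemble an evaluation report
#'
#' Combines per-label review counts into the standard evaluation report:
#' per-label precision, overall precision, recall from the sampled
#' false-negative count, inter-annotator kappa and the corpus noncompliance
#' rate.
#'
#' @param tp named numeric vector of confirmed counts per noncompliance
#'   label.
#' @param flagged_n named numeric vector of flagged counts per label (same
#'   names).
#' @param fn number of noncompliance messages found in the review sample of
#'   the other topics (false negatives).
#' @param sampled_other_n size of that review sample.
#' @param assigned_total total number of topic-assigned messages (for the
#'   noncompliance rate).
#' @param kappa_table optional 2 x 2 inter-annotator agreement table.
#' @return list of class `"nonadh_evaluation"`.
#' @export
evaluation_report <- function(tp, flagged_n, fn, sampled_other_n = NA_integer_,
                              assigned_total = NA_integer_,
                              kappa_table = NULL) {
  stopifnot(identical(sort(names(tp)), sort(names(flagged_n))))
  flagged_n <- flagged_n[names(tp)]
  per_label <- data.frame(
    label = names(tp),
    flagged_n = as.numeric(flagged_n),
    tp = as.numeric(tp),
    precision = vapply(names(tp),
                       function(l) precision_pct(tp[[l]], flagged_n[[l]]),
                       numeric(1)),
    row.names = NULL
  )
  tp_total <- sum(tp)
  structure(list(
    per_label = per_label,
    tp_total = tp_total,
    flagged_total = sum(flagged_n),
    precision_overall = precision_pct(tp_total, sum(flagged_n)),
    fn = fn,
    sampled_other_n = sampled_other_n,
    recall = recall_pct(tp_total, fn),
    kappa = if (!is.null(kappa_table)) cohen_kappa(kappa_table) else NA_real_,
    noncompliance_rate =
      if (!is.na(assigned_total)) noncompliance_rate(tp_total, assigned_total)
      else NA_real_
  ), class = "nonadh_evaluation")
}

#' @export
print.nonadh_evaluation <- function(x, ...) {
  cat("Noncompliance detection evaluation\n")
  print(x$per_label, row.names = FALSE)
  cat(sprintf("Overall precision: %s%% (%d/%d)\n",
              format(x$precision_overall), x$tp_total, x$flagged_total))
  cat(sprintf("Recall: %s%% (%d/%d)\n", format(x$recall), x$tp_total,
              x$tp_total + x$fn))
  if (!is.na(x$kappa)) cat(sprintf("Cohen kappa: %.3f\n", x$kappa))
  if (!is.na(x$noncompliance_rate)) {
    cat(sprintf("Noncompliance rate: %.2f%%\n", x$noncompliance_rate))
  }
  invisible(x)
}
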