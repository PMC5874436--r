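# Message-topic assignment by the token-fraction rule and extraction of
# messages flagged by noncompliance-labeled topics.

#' Topic association of a single token
#'
#' A token occurrence of term `v` in document `d` is associated with the
#' topic maximizing `theta[d, k] * phi[k, v]` (the MAP topic of the token
#' under the fitted model). Ties go to the lowest topic index.
#'
#' @param model a fitted `"lda_map"` object.
#' @param d document index or document id.
#' @param v term string or vocabulary index.
#' @return integer topic index.
#' @export
token_topic <- function(model, d, v) {
  stopifnot(inherits(model, "lda_map"))
  if (is.character(d)) d <- match(d, model$doc_ids)
  if (is.na(d) || d < 1L || d > nrow(model$theta)) stop("unknown document")
  if (is.character(v)) {
    vi <- match(v, model$vocabulary)
    if (is.na(vi)) stop("term not in vocabulary: ", v)
    v <- vi
  }
  as.integer(which.max(model$theta[d, ] * model$phi[, v]))
}

# Fold in a new document: EM over its topic weights with phi fixed.
.fold_in_theta <- function(model, counts, iters = 100L) {
  K <- model$K
  a_t <- model$alpha_theta
  theta <- rep(1 / K, K)
  vidx <- which(counts > 0)
  x <- counts[vidx]
  phi_sub <- model$phi[, vidx, drop = FALSE]
  for (i in seq_len(iters)) {
    s <- as.vector(theta %*% phi_sub)
    theta_new <- theta * as.vector(phi_sub %*% (x / pmax(s, 1e-300))) + (a_t - 1)
    theta_new <- pmax(theta_new, 1e-12)
    theta_new <- theta_new / sum(theta_new)
    if (max(abs(theta_new - theta)) < 1e-10) { theta <- theta_new; break }
    theta <- theta_new
  }
  theta
}

#' Assign messages to topics by the token-fraction rule
#'
#' For each document, every in-vocabulary token occurrence is associated with
#' its MAP topic ([token_topic()]); `f[k]` is the fraction of the document's
#' in-vocabulary token occurrences associated with topic `k` (repeated
#' occurrences count multiply; out-of-vocabulary tokens are excluded from the
#' denominator). The document is assigned to every topic with
#' `f[k] >= tau`. Documents with no in-vocabulary token get all-zero
#' fractions and an empty assignment.
#'
#' Documents whose `message_id` matches a fitted document use the fitted
#' topic weights; unseen documents are folded in by EM over the topic
#' weights with the topic-term distributions held fixed.
#'
#' @param model a fitted `"lda_map"` object.
#' @param docs list of tokenized documents (`message_id`, `tokens`).
#' @param tau association threshold (default 0.25).
#' @return an object of class `"nonadh_assignments"`: list with `message_id`,
#'   `token_fractions` (documents x K matrix) and `assigned` (list of integer
#'   topic sets).
#' @export
assign_corpus <- function(model, docs, tau = 0.25) {
  stopifnot(inherits(model, "lda_map"), tau > 0, tau <= 1)
  D <- length(docs)
  K <- model$K
  ids <- vapply(docs, function(d) as.character(d$message_id), character(1))
  frac <- matrix(0, nrow = D, ncol = K)
  assigned <- vector("list", D)
  for (i in seq_len(D)) {
    vidx <- match(docs[[i]]$tokens, model$vocabulary)
    vidx <- vidx[!is.na(vidx)]
    if (length(vidx) == 0L) {
      assigned[[i]] <- integer(0)
      next
    }
    di <- match(ids[i], model$doc_ids)
    theta_d <- if (!is.na(di)) {
      model$theta[di, ]
    } else {
      cnt <- tabulate(vidx, nbins = length(model$vocabulary))
      .fold_in_theta(model, cnt)
    }
    uq <- sort(unique(vidx))
    cnt <- tabulate(match(vidx, uq), nbins = length(uq))
    # MAP topic per unique term; ties resolved to the lowest topic index
    scores <- theta_d * model$phi[, uq, drop = FALSE]
    tt <- max.col(t(scores), ties.method = "first")
    f <- vapply(seq_len(K), function(k) sum(cnt[tt == k]), numeric(1))
    f <- f / sum(cnt)
    frac[i, ] <- f
    assigned[[i]] <- which(f >= tau)
  }
  structure(list(message_id = ids, token_fractions = frac,
                 assigned = assigned, tau = tau),
            class = "nonadh_assignments")
}

#' Assign one tokenized document
#'
#' Single-document convenience wrapper around [assign_corpus()].
#'
#' @inheritParams assign_corpus
#' @param doc a tokenized document (`message_id`, `tokens`).
#' @return list with `message_id`, `token_fractions` (length-K vector) and
#'   `assigned` (integer topic set).
#' @export
assign_document <- function(model, doc, tau = 0.25) {
  a <- assign_corpus(model, list(doc), tau = tau)
  list(message_id = a$message_id[1L],
       token_fractions = a$token_fractions[1L, ],
       assigned = a$assigned[[1L]])
}

#' Predict topic assignments from a fitted model
#'
#' @param object a fitted `"lda_map"` object.
#' @param newdata list of tokenized documents.
#' @param tau association threshold.
#' @param ... unused.
#' @return see [assign_corpus()].
#' @export
predict.lda_map <- function(object, newdata, tau = 0.25, ...) {
  assign_corpus(object, newdata, tau = tau)
}

#' @export
print.nonadh_assignments <- function(x, ...) {
  n_ass <- lengths(x$assigned)
  cat(sprintf("Topic assignments: %d messages, tau = %g, %d unassigned\n",
              length(x$message_id), x$tau, sum(n_ass == 0L)))
  invisible(x)
}

#' Summary statistics of topic assignments
#'
#' Per-topic message counts and proportions (relative to the total message
#' count), the number of unassigned messages, and the mean and median number
#' of topics per message over the assigned messages only (reported as `NA`
#' when no message is assigned).
#'
#' @param assignments a `"nonadh_assignments"` object.
#' @return list with `topic_counts`, `topic_proportions`, `n_messages`,
#'   `n_unassigned`, `mean_topics_per_message`, `median_topics_per_message`.
#' @export
assignment_stats <- function(assignments) {
  stopifnot(inherits(assignments, "nonadh_assignments"))
  K <- ncol(assignments$token_fractions)
  D <- length(assignments$message_id)
  sizes <- lengths(assignments$assigned)
  counts <- tabulate(unlist(assignments$assigned), nbins = K)
  assigned_sizes <- sizes[sizes > 0L]
  list(topic_counts = counts,
       topic_proportions = if (D > 0L) counts / D else rep(NA_real_, K),
       n_messages = D,
       n_unassigned = sum(sizes == 0L),
       mean_topics_per_message =
         if (length(assigned_sizes)) mean(assigned_sizes) else NA_real_,
       median_topics_per_message =
         if (length(assigned_sizes)) stats::median(assigned_sizes) else NA_real_)
}

#' Read a topic-label map
#'
#' CSV (columns `topic`, `label`) or YAML (mapping of topic id to label).
#'
#' @param path file path.
#' @return named character vector, names are topic ids.
#' @export
read_topic_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    m <- yaml::read_yaml(path)
    labels <- vapply(m, as.character, character(1))
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    stopifnot(all(c("topic", "label") %in% names(df)))
    labels <- df$label
    names(labels) <- df$topic
  }
  if (anyDuplicated(names(labels))) stop("duplicate topic id in label map")
  labels
}

#' Extract messages flagged by noncompliance topics
#'
#' Returns, per noncompliance label, the set of message ids assigned to any
#' topic carrying that label, plus the intersection across the noncompliance
#' labels and the union (all flagged messages).
#'
#' @param assignments a `"nonadh_assignments"` object.
#' @param labels named character vector mapping topic index (as name) to
#'   label; the distinguished labels are `"dosage_variation"` and
#'   `"treatment_cessation"`.
#' @param noncompliance_labels labels counted as noncompliance.
#' @return list with `by_label` (list of message-id vectors per label),
#'   `intersection` (ids flagged by more than one noncompliance label) and
#'   `flagged` (union of all noncompliance ids).
#' @export
extract_flagged <- function(assignments, labels,
                            noncompliance_labels = c("dosage_variation",
                                                     "treatment_cessation")) {
  stopifnot(inherits(assignments, "nonadh_assignments"))
  by_label <- list()
  for (lab in noncompliance_labels) {
    topics <- as.integer(names(labels)[labels == lab])
    if (length(topics) == 0L) {
      warning("no topic labeled '", lab, "'")
      by_label[[lab]] <- character(0)
      next
    }
    sel <- vapply(assignments$assigned,
                  function(s) any(topics %in% s), logical(1))
    by_label[[lab]] <- assignments$message_id[sel]
  }
  inter <- if (length(by_label) >= 2L) Reduce(intersect, by_label)
           else character(0)
  list(by_label = by_label,
       intersection = inter,
       flagged = unique(unlist(by_label, use.names = FALSE)))
}
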