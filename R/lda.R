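# Latent Dirichlet allocation fitted by maximum-a-posteriori EM, with a
# penalized-likelihood approximation to the log marginal and log-Bayes-factor
# selection of the number of topics.

# Run expr with a local RNG seeded at `seed`, restoring global RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rdirichlet_rows <- function(n, dim, conc) {
  g <- matrix(stats::rgamma(n * dim, shape = conc), nrow = n)
  g <- pmax(g, 1e-300)
  g / rowSums(g)
}

# Accepts a nonadh_dtm (integer counts), a nonadh_weighted (TF-IDF weights,
# rounded x10 to integers so the multinomial likelihood applies), or a plain
# nonnegative matrix.
.lda_input_matrix <- function(x) {
  if (inherits(x, "nonadh_dtm")) {
    list(X = as.matrix(x$counts), doc_ids = x$doc_ids, vocab = x$vocabulary)
  } else if (inherits(x, "nonadh_weighted")) {
    X <- round(as.matrix(x$values) * 10)
    list(X = X, doc_ids = x$doc_ids, vocab = x$vocabulary)
  } else {
    X <- as.matrix(x)
    if (any(X < 0)) stop("input matrix must be nonnegative")
    list(X = X,
         doc_ids = if (!is.null(rownames(X))) rownames(X)
                   else sprintf("doc%d", seq_len(nrow(X))),
         vocab = if (!is.null(colnames(X))) colnames(X)
                 else sprintf("term%d", seq_len(ncol(X))))
  }
}

# Log posterior density: multinomial log likelihood plus the full (normalized)
# symmetric Dirichlet log densities of every theta and phi row, so values are
# comparable across K.
.log_posterior <- function(X, theta, phi, a_t, a_p) {
  S <- theta %*% phi
  ll <- sum(X * log(pmax(S, 1e-300)))
  D <- nrow(theta); K <- ncol(theta); V <- ncol(phi)
  pr_t <- D * (lgamma(K * a_t) - K * lgamma(a_t)) +
    (a_t - 1) * sum(log(pmax(theta, 1e-300)))
  pr_p <- K * (lgamma(V * a_p) - V * lgamma(a_p)) +
    (a_p - 1) * sum(log(pmax(phi, 1e-300)))
  ll + pr_t + pr_p
}

.lda_em_once <- function(X, K, a_t, a_p, seed, tol, max_iter) {
  D <- nrow(X); V <- ncol(X)
  # theta starts uniform so the fit is equivariant under document
  # permutation; symmetry is broken by the seeded random phi draw
  theta <- matrix(1 / K, nrow = D, ncol = K)
  phi <- .with_seed(seed, .rdirichlet_rows(K, V, 1.5))
  trace <- .log_posterior(X, theta, phi, a_t, a_p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    S <- theta %*% phi
    R <- X / pmax(S, 1e-300)
    theta_new <- theta * (R %*% t(phi)) + (a_t - 1)
    theta_new <- pmax(theta_new, 1e-12)
    theta_new <- theta_new / rowSums(theta_new)
    phi_new <- phi * (t(theta) %*% R) + (a_p - 1)
    phi_new <- pmax(phi_new, 1e-12)
    phi_new <- phi_new / rowSums(phi_new)
    theta <- theta_new; phi <- phi_new
    lp <- .log_posterior(X, theta, phi, a_t, a_p)
    trace <- c(trace, lp)
    prev <- trace[length(trace) - 1L]
    if (abs(lp - prev) / (abs(prev) + 1) < tol) { converged <- TRUE; break }
  }
  list(theta = theta, phi = phi, trace = trace, converged = converged)
}

#' Fit latent Dirichlet allocation by maximum a posteriori EM
#'
#' Fits the LDA model by EM on the MAP objective: the E-step computes topic
#' responsibilities `r[d,v,k]` proportional to `theta[d,k] * phi[k,v]`, the
#' M-step re-estimates `theta[d,k]` proportional to
#' `sum_v x[d,v] r[d,v,k] + (alpha_theta - 1)` and `phi[k,v]` proportional to
#' `sum_d x[d,v] r[d,v,k] + (alpha_phi - 1)` (floored at 1e-12 before
#' normalization). Iteration stops when the relative log-posterior change
#' falls below `tol`. Initial topic weights are uniform (so fits are
#' equivariant under document permutation) and initial topic-term rows are
#' drawn from a symmetric Dirichlet(1.5) with the run seed. Several seeded
#' restarts are run and the best log-posterior fit kept. At `K = 1` the exact closed form is used: `phi` is
#' the prior-smoothed normalized corpus term-frequency vector and every
#' `theta` is exactly 1.
#'
#' @param x a `"nonadh_dtm"` (counts), a `"nonadh_weighted"` (TF-IDF weights,
#'   rounded x10 to integer pseudo-counts), or a nonnegative matrix with no
#'   all-zero row.
#' @param K number of topics (>= 1).
#' @param alpha_theta,alpha_phi symmetric Dirichlet hyperparameters, > 1 so a
#'   strictly interior MAP exists. Default 1.1.
#' @param seed integer seed; restart `i` uses `seed + i - 1`.
#' @param tol relative log-posterior convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of seeded initializations.
#' @return an object of class `"lda_map"` with elements `K`, `phi` (K x V
#'   topic-term probabilities), `theta` (D x K document-topic probabilities),
#'   `alpha_theta`, `alpha_phi`, `log_posterior_trace`, `log_posterior`,
#'   `log_marginal`, `df`, `N`, `seed`, `n_restarts`, `converged`,
#'   `doc_ids` and `vocabulary`.
#' @seealso [select_num_topics()], [top_terms()], [predict.lda_map()]
#' @export
lda_map <- function(x, K, alpha_theta = 1.1, alpha_phi = 1.1, seed = 1L,
                    tol = 1e-6, max_iter = 200L, n_restarts = 3L) {
  stopifnot(K >= 1L, alpha_theta > 1, alpha_phi > 1, n_restarts >= 1L)
  inp <- .lda_input_matrix(x)
  X <- inp$X
  D <- nrow(X); V <- ncol(X)
  if (any(rowSums(X) == 0)) {
    stop("input has all-zero row(s); call drop_empty_documents() first")
  }
  if (K > V) warning("K exceeds the vocabulary size")
  if (K == 1L) {
    phi <- matrix((colSums(X) + alpha_phi - 1) /
                    (sum(X) + V * (alpha_phi - 1)), nrow = 1)
    theta <- matrix(1, nrow = D, ncol = 1)
    lp <- .log_posterior(X, theta, phi, alpha_theta, alpha_phi)
    best <- list(theta = theta, phi = phi, trace = lp, converged = TRUE)
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- .lda_em_once(X, K, alpha_theta, alpha_phi,
                          seed = seed + r - 1L, tol = tol,
                          max_iter = max_iter)
      if (is.null(best) ||
          fit$trace[length(fit$trace)] > best$trace[length(best$trace)]) {
        best <- fit
      }
    }
  }
  lp <- best$trace[length(best$trace)]
  df <- K * (V - 1) + D * (K - 1)
  N <- sum(X)
  dimnames(best$phi) <- list(NULL, inp$vocab)
  dimnames(best$theta) <- list(inp$doc_ids, NULL)
  structure(list(
    K = as.integer(K),
    phi = best$phi,
    theta = best$theta,
    alpha_theta = alpha_theta,
    alpha_phi = alpha_phi,
    log_posterior_trace = best$trace,
    log_posterior = lp,
    log_marginal = lp - df / 2 * log(N),
    df = df,
    N = N,
    seed = as.integer(seed),
    n_restarts = as.integer(n_restarts),
    converged = best$converged,
    doc_ids = inp$doc_ids,
    vocabulary = inp$vocab
  ), class = "lda_map")
}

#' Approximate log marginal likelihood of a fitted topic model
#'
#' BIC-style (Laplace-type) approximation: the maximized log posterior minus
#' the dimensionality penalty `(df / 2) * log(N)` with
#' `df = K (V - 1) + D (K - 1)` free parameters and `N` the total token
#' count. Used to form log Bayes factors against the one-topic model.
#'
#' @param model a fitted `"lda_map"` object.
#' @return a number (the approximate log marginal likelihood).
#' @export
log_marginal_approx <- function(model) {
  if (!inherits(model, "lda_map") || is.null(model$log_marginal)) {
    stop("`model` must be a fitted lda_map object")
  }
  model$log_marginal
}

#' Select the number of topics by log Bayes factor
#'
#' Fits the model for every `K` in `config$K_grid` (sharing the configured
#' seed policy) and computes the log Bayes factor
#' `BF(K) = log_marginal(K) - log_marginal(1)` against the one-topic model.
#' The selected `K` maximizes `BF` over the grid; if no `K` attains a
#' positive `BF`, the one-topic model is selected.
#'
#' @param x model input as in [lda_map()].
#' @param config a [run_config()] list (fields `K_grid`, `seed`,
#'   `alpha_theta`, `alpha_phi`, `tol`, `max_iter`, `n_restarts`).
#' @return an object of class `"lda_selection"`: list with `K_grid`,
#'   `bf_table` (data frame of K, log_marginal, log_bf), `selected`, `model`
#'   (the fit at the selected K) and `errors` (per-K failure messages, if
#'   any).
#' @export
select_num_topics <- function(x, config = run_config()) {
  K_grid <- sort(unique(as.integer(config$K_grid)))
  if (length(K_grid) == 0L) stop("K_grid is empty")
  fit_one <- function(K) {
    tryCatch(lda_map(x, K,
                     alpha_theta = config$alpha_theta,
                     alpha_phi = config$alpha_phi,
                     seed = config$seed, tol = config$tol,
                     max_iter = config$max_iter,
                     n_restarts = config$n_restarts),
             error = function(e) conditionMessage(e))
  }
  fits <- lapply(K_grid, fit_one)
  names(fits) <- as.character(K_grid)
  ref <- if ("1" %in% names(fits) && inherits(fits[["1"]], "lda_map")) {
    fits[["1"]]
  } else {
    fit_one(1L)
  }
  if (!inherits(ref, "lda_map")) stop("one-topic reference fit failed: ", ref)
  lm1 <- ref$log_marginal
  ok <- vapply(fits, inherits, logical(1), what = "lda_map")
  lms <- rep(NA_real_, length(fits))
  lms[ok] <- vapply(fits[ok], function(f) f$log_marginal, numeric(1))
  bf <- lms - lm1
  bf_table <- data.frame(K = K_grid, log_marginal = lms, log_bf = bf)
  cand <- which(ok & !is.na(bf))
  if (length(cand) == 0L) stop("every candidate fit failed")
  if (all(bf[cand] <= 0)) {
    selected <- 1L
    model <- ref
  } else {
    best <- cand[which.max(bf[cand])]
    selected <- K_grid[best]
    model <- fits[[best]]
  }
  errors <- unlist(fits[!ok])
  structure(list(K_grid = K_grid, bf_table = bf_table,
                 selected = as.integer(selected), model = model,
                 errors = if (length(errors)) errors else NULL),
            class = "lda_selection")
}

#' Top terms of a topic
#'
#' The `n` terms with the largest probability under topic `k`, in descending
#' order, ties broken alphabetically. Topics are conventionally interpreted
#' and labeled from their first 15 terms.
#'
#' @param model a fitted `"lda_map"` object.
#' @param k topic index in `1..K`.
#' @param n number of terms (capped at the vocabulary size).
#' @return character vector of terms.
#' @export
top_terms <- function(model, k, n = 15L) {
  stopifnot(inherits(model, "lda_map"), n >= 1L)
  if (k < 1L || k > model$K) stop("topic index out of range: ", k)
  ord <- order(-model$phi[k, ], model$vocabulary, method = "radix")
  model$vocabulary[ord][seq_len(min(n, length(model$vocabulary)))]
}

#' @export
print.lda_map <- function(x, ...) {
  cat(sprintf("LDA model (MAP-EM): K = %d topics, %d documents, %d terms\n",
              x$K, nrow(x$theta), length(x$vocabulary)))
  cat(sprintf("  log posterior %.2f, approx. log marginal %.2f, %s\n",
              x$log_posterior, x$log_marginal,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.lda_map <- function(object, n = 15L, ...) {
  tt <- vapply(seq_len(object$K), function(k) {
    tts <- top_terms(object, k, n)
    length(tts) <- min(n, length(object$vocabulary))
    tts
  }, character(min(n, length(object$vocabulary))))
  colnames(tt) <- sprintf("topic_%d", seq_len(object$K))
  structure(list(model = object, top_terms = tt,
                 topic_mass = colMeans(object$theta)),
            class = "summary.lda_map")
}

#' @export
print.summary.lda_map <- function(x, ...) {
  print(x$model)
  cat("Mean document-topic weight:\n")
  print(round(x$topic_mass, 4))
  cat("Top terms per topic:\n")
  print(x$top_terms, quote = FALSE)
  invisible(x)
}

#' @export
coef.lda_map <- function(object, which = c("phi", "theta"), ...) {
  which <- match.arg(which)
  object[[which]]
}

#' @export
logLik.lda_map <- function(object, ...) {
  structure(object$log_posterior, df = object$df, nobs = object$N,
            class = "logLik")
}

#' @export
plot.lda_map <- function(x, ...) {
  graphics::plot(seq_along(x$log_posterior_trace) - 1L,
                 x$log_posterior_trace, type = "b", pch = 16, cex = 0.6,
                 xlab = "EM iteration", ylab = "log posterior",
                 main = sprintf("MAP-EM trace (K = %d)", x$K), ...)
  invisible(x)
}

#' Simulate token documents from a fitted model
#'
#' Draws documents from the fitted generative process: for each document its
#' fitted topic weights are used, a length is drawn from a Poisson with the
#' document's observed token total as mean, and tokens are drawn topic-first.
#'
#' @param object a fitted `"lda_map"` object.
#' @param nsim number of simulated corpora.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` corpora, each a list of tokenized documents.
#' @export
simulate.lda_map <- function(object, nsim = 1, seed = object$seed, ...) {
  doc_tot <- round(object$N * object$theta %*% rep(1, object$K) /
                     nrow(object$theta))
  .with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      lapply(seq_len(nrow(object$theta)), function(d) {
        len <- max(1L, stats::rpois(1, doc_tot[d]))
        z <- sample.int(object$K, len, replace = TRUE,
                        prob = object$theta[d, ])
        toks <- vapply(z, function(k) {
          sample(object$vocabulary, 1L, prob = object$phi[k, ])
        }, character(1))
        list(message_id = object$doc_ids[d], tokens = toks)
      })
    })
  })
}

#' @export
print.lda_selection <- function(x, ...) {
  cat(sprintf("Topic-number selection by log Bayes factor: selected K = %d\n",
              x$selected))
  print(x$bf_table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.lda_selection <- function(x, ...) {
  graphics::plot(x$bf_table$K, x$bf_table$log_bf, type = "b", pch = 16,
                 xlab = "number of topics K",
                 ylab = "log Bayes factor vs one-topic model",
                 main = "Topic-number selection", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = x$selected, lty = 2, col = "red")
  invisible(x)
}
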