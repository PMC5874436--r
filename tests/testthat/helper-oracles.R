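# Independent oracles used by the tests.

# Cohen kappa by explicit expected-agreement-from-marginal-products loops,
# independent of the package implementation.
oracle_kappa <- function(tab) {
  n <- sum(tab)
  k <- nrow(tab)
  p_o <- 0
  for (i in seq_len(k)) p_o <- p_o + tab[i, i] / n
  p_e <- 0
  for (i in seq_len(k)) {
    row_i <- sum(tab[i, ]) / n
    col_i <- sum(tab[, i]) / n
    p_e <- p_e + row_i * col_i
  }
  (p_o - p_e) / (1 - p_e)
}

# Log posterior of an LDA parameter point (same objective the fitter
# maximizes), written independently.
oracle_log_posterior <- function(X, theta, phi, a_t, a_p) {
  D <- nrow(theta); K <- ncol(theta); V <- ncol(phi)
  ll <- 0
  for (d in seq_len(D)) {
    for (v in seq_len(V)) {
      if (X[d, v] > 0) {
        s <- sum(theta[d, ] * phi[, v])
        ll <- ll + X[d, v] * log(s)
      }
    }
  }
  ll + D * (lgamma(K * a_t) - K * lgamma(a_t)) + (a_t - 1) * sum(log(theta)) +
    K * (lgamma(V * a_p) - V * lgamma(a_p)) + (a_p - 1) * sum(log(phi))
}

# Grid-search oracle for the 2-document, K = 2 MAP optimum: exhaustive grid
# over the two document-topic weights; for each grid point the topic-term
# rows are solved by a fixed-point ascent (the objective is concave in phi
# for fixed theta, so the inner solve reaches the global inner optimum).
oracle_map_grid <- function(X, a_t, a_p, n_grid = 50L, inner_iter = 200L) {
  stopifnot(nrow(X) == 2L)
  V <- ncol(X)
  grid <- seq(0.005, 0.995, length.out = n_grid)
  best <- -Inf
  for (t1 in grid) {
    for (t2 in grid) {
      theta <- rbind(c(t1, 1 - t1), c(t2, 1 - t2))
      phi <- matrix(1 / V, nrow = 2, ncol = V)
      for (it in seq_len(inner_iter)) {
        S <- theta %*% phi
        R <- X / pmax(S, 1e-300)
        phi_new <- phi * (t(theta) %*% R) + (a_p - 1)
        phi_new <- pmax(phi_new, 1e-12)
        phi_new <- phi_new / rowSums(phi_new)
        if (max(abs(phi_new - phi)) < 1e-12) { phi <- phi_new; break }
        phi <- phi_new
      }
      lp <- oracle_log_posterior(X, theta, phi, a_t, a_p)
      if (lp > best) best <- lp
    }
  }
  best
}

# A hand-built model object whose token-topic map is fully controlled:
# term i belongs deterministically to topic i (phi concentrated), theta
# uniform for every document.
hand_model <- function(K, terms, doc_ids = "d1") {
  stopifnot(length(terms) == K)
  phi <- matrix(1e-6, nrow = K, ncol = K, dimnames = list(NULL, terms))
  diag(phi) <- 1
  phi <- phi / rowSums(phi)
  theta <- matrix(1 / K, nrow = length(doc_ids), ncol = K,
                  dimnames = list(doc_ids, NULL))
  structure(list(K = K, phi = phi, theta = theta,
                 alpha_theta = 1.1, alpha_phi = 1.1,
                 doc_ids = doc_ids, vocabulary = terms,
                 log_posterior = 0, log_marginal = 0, df = 0, N = 0,
                 seed = 1L, n_restarts = 1L, converged = TRUE),
            class = "lda_map")
}

toy_corpus_path <- function() {
  system.file("extdata", "toy", "corpus.jsonl", package = "nonadh")
}

toy_config <- function(...) {
  run_config(drug_names = c("seroplex", "escitalopram"), ...)
}
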