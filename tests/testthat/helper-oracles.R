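# Independent oracles, deliberately implemented apart from the package:
# log-choose enumeration for Fisher, Newton-Raphson for the weighted MLE,
# pair counting for AUC, and the two-normal density ratio for Wakefield.

oracle_fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lp <- function(x) lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  sup <- max(0, k - m2):min(k, m1)
  probs <- exp(vapply(sup, lp, numeric(1)))
  p0 <- exp(lp(a))
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

oracle_weighted_mle <- function(X, y, w, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    p <- stats::plogis(drop(X1 %*% beta))
    g <- drop(t(X1) %*% (w * (y - p)))
    H <- t(X1) %*% (X1 * (w * p * (1 - p)))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

oracle_wakefield <- function(beta, se, prior_sd) {
  stats::dnorm(beta, 0, sqrt(se^2 + prior_sd^2)) / stats::dnorm(beta, 0, se)
}

# small helper: annotation matrix from a plain matrix of 0/1 values
toy_am <- function(values, mode = "binary", clump_group = NA_character_) {
  annotation_matrix(values, feature_defs(colnames(values), mode, clump_group))
}
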