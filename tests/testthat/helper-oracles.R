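# Independent brute-force oracles, kept deliberately naive.

# Exact one-sided signed-rank p by enumerating all 2^n sign assignments of the
# observed |d| (valid for tie-free, zero-free differences).
oracle_signed_rank_p <- function(d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# Kendall tau-b by O(n^2) pair counting with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Quadratic-form elastic-net objective, for direct minimization checks.
oracle_enet_objective <- function(X, y, b0, beta, alpha, lambda) {
  n <- nrow(X)
  sum((y - b0 - X %*% beta)^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}
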