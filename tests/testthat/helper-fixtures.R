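# Small in-code fixtures shared across tests

# cohort small enough for sub-second CV runs
small_cohort <- function(seed = 7, n = 60L, n_nodes = 20L, beta = 0.2,
                         n_planted = 15L, retention = FALSE) {
  generate_cohort(
    n = n, n_nodes = n_nodes,
    truth = truth_config(n_planted = n_planted, beta = beta),
    retention_6m = if (retention) 0.84 else 1,
    retention_14m = if (retention) 0.821 else 1,
    seed = seed)
}

# two series with an exact target Pearson correlation, by orthogonalization
correlated_pair <- function(r, t = 24L, seed = 1L) {
  set.seed(seed)
  x <- rnorm(t)
  b <- rnorm(t)
  xs <- as.numeric(scale(x))
  bres <- as.numeric(scale(residuals(lm(b ~ xs))))
  y <- r * xs + sqrt(1 - r^2) * bres
  cbind(a = x, b = y)
}

# independent brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# residualize-both-then-correlate oracle for partial correlation
partial_corr_oracle <- function(e, y, X) {
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(cor(e, y))
  df <- data.frame(X)
  re <- residuals(lm(e ~ ., data = df))
  ry <- residuals(lm(y ~ ., data = df))
  cor(re, ry)
}
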