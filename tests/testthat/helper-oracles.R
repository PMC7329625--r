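# Independent oracles used across the suite.  These are deliberately
# naive implementations that share no code with the package internals.

# Exhaustive basic-solution search for the pinball-loss minimum: every
# optimal quantile regression interpolates p observations, so the global
# minimum is attained on one of the choose(n, p) exact-fit bases.
lattice_pinball_min <- function(X, y, tau) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  pin <- function(u) sum(u * (tau - (u < 0)))
  best <- Inf
  bases <- combn(n, p)
  for (j in seq_len(ncol(bases))) {
    idx <- bases[, j]
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- solve(Xi, y[idx])
    l <- pin(y - X %*% b)
    if (l < best) best <- l
  }
  best
}

# brute-force weighted sum for polygenic scores
prs_bruteforce <- function(weights, dosages) {
  out <- numeric(ncol(dosages))
  for (s in seq_len(ncol(dosages))) {
    acc <- 0
    for (v in seq_len(nrow(dosages))) acc <- acc + weights[v] * dosages[v, s]
    out[s] <- acc
  }
  out
}

# direct local-linear smoother with tricube weights (plain implementation
# of the loess definition for a 1-d predictor, no interpolation surface)
local_linear_tricube <- function(x, y, span, at = x) {
  n <- length(x)
  k <- max(2, ceiling(span * n))
  vapply(at, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[k]
    w <- (1 - pmin(d / h, 1)^3)^3
    keep <- w > 0
    fit <- lm(y ~ x, weights = w, subset = keep)
    unname(predict(fit, data.frame(x = x0)))
  }, numeric(1))
}

# small cohort for coding/pipeline tests
toy_cohort <- function(n = 40, seed = 42) {
  cfg <- sim_config(n, age_groups = c(7, 10),
                    factors = list(factor_spec("expo", 0.5, -0.3, 0)),
                    mu0 = 0, sigma0 = 1, error_shape = "normal",
                    seed = seed)
  simulate_cohort(cfg)
}
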