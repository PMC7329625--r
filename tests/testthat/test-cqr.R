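test_that("pinball loss evaluates the check function", {
  expect_equal(pinball_loss(c(0, 0, 0), 0.3), 0)
  expect_equal(pinball_loss(c(1, -1), 0.5), 1)
  expect_equal(pinball_loss(c(1, -1), 0.05), 1)
  expect_equal(pinball_loss(c(2, -1), 0.05), 1.05)
  expect_error(pinball_loss(1, 0), "tau")
  expect_error(pinball_loss(1, 1), "tau")
})

test_that("intercept-only median fit returns the sample median", {
  d <- data.frame(y = c(1, 2, 3))
  expect_equal(unname(coef(cqr(y ~ 1, d, tau = 0.5))), 2)
})

test_that("saturated binary fit equals group quantiles", {
  d <- data.frame(y = c(0, 1, 2, 10, 11, 12), x = rep(0:1, each = 3))
  f <- cqr(y ~ x, d, tau = 0.5)
  expect_equal(unname(coef(f)), c(1, 10))
  expect_equal(group_quantile_oracle(d$y, d$x, 0.5), 10)
  expect_equal(group_quantile_oracle(c(0, 1, 2, 0, 1, 2),
                                     rep(0:1, each = 3), 0.5), 0)
  expect_error(group_quantile_oracle(c(0, 1), c(0, 0), 0.5), "empty group")
})

test_that("achieved loss matches the exhaustive basis search", {
  set.seed(101)
  for (rep in 1:8) {
    n <- 11
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
    y <- 0.5 + x1 - 0.8 * x2 + rnorm(n)
    d <- data.frame(y = y, x1 = x1, x2 = x2)
    for (tau in c(0.05, 0.3, 0.5, 0.8)) {
      fit <- cqr(y ~ x1 + x2, d, tau = tau)
      oracle <- lattice_pinball_min(cbind(1, x1, x2), y, tau)
      expect_lt(abs(fit$loss - oracle) / max(oracle, 1e-12), 1e-6)
    }
  }
})

test_that("fit is equivariant to location and scale of the response", {
  set.seed(7)
  d <- data.frame(y = rnorm(101), x = rbinom(101, 1, 0.5))
  base <- coef(cqr(y ~ x, d, tau = 0.25))
  shifted <- coef(cqr(y ~ x, transform(d, y = y + 5), tau = 0.25))
  expect_equal(unname(shifted["x"]), unname(base["x"]), tolerance = 1e-8)
  expect_equal(unname(shifted["(Intercept)"]),
               unname(base["(Intercept)"]) + 5, tolerance = 1e-8)
  scaled <- coef(cqr(y ~ x, transform(d, y = 3 * y), tau = 0.25))
  expect_equal(unname(scaled), unname(3 * base), tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  d <- data.frame(y = rnorm(20), x = rbinom(20, 1, 0.5))
  d$z <- d$x
  expect_error(cqr(y ~ x + z, d, tau = 0.5), "collinear.*z")
})

test_that("grid fits are flat under a pure location shift", {
  cfg <- sim_config(4000, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.5, 0)),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 20)
  tab <- simulate_cohort(cfg)
  g <- cqr_grid(refractive_error ~ f, tab)
  expect_equal(nrow(g$effects), 19)
  # location-shift model: effects constant across tau up to sampling noise
  expect_lt(max(g$effects$beta) - min(g$effects$beta), 0.25)
  expect_lt(abs(median(g$effects$beta) + 0.5), 0.1)
  # grid of length 1 reduces to a single fit
  g1 <- cqr_grid(refractive_error ~ f, tab, taus = 0.5)
  expect_equal(g1$effects$beta,
               unname(coef(cqr(refractive_error ~ f, tab, tau = 0.5))["f"]))
})

test_that("location-scale data give amplified tail effects on the grid", {
  cfg <- sim_config(4000, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.125, log(2))),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 21)
  tab <- simulate_cohort(cfg)
  g <- cqr_grid(refractive_error ~ f, tab, taus = c(0.05, 0.5))
  expect_lt(g$effects$beta[1], g$effects$beta[2])   # more negative in tail
})

test_that("median fit with symmetric noise approximates OLS", {
  cfg <- sim_config(20000, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.3, 0)),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 22)
  tab <- simulate_cohort(cfg)
  b_cqr <- unname(coef(cqr(refractive_error ~ f, tab, tau = 0.5))["f"])
  b_ols <- fit_ols(refractive_error ~ f, tab)$beta
  expect_lt(abs(b_cqr - b_ols), 0.05)
})

test_that("OLS fit reproduces closed-form least squares", {
  d <- data.frame(y = c(1.2, 0.8, 2.1, 1.9, 3.2, 2.8),
                  x = c(0, 0, 1, 1, 2, 2))
  est <- fit_ols(y ~ x, d)
  X <- cbind(1, d$x)
  bh <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(est$beta, bh[2, 1], tolerance = 1e-12)
  # saturated binary: slope = difference of group means
  d2 <- data.frame(y = c(0, 1, 2, 10, 11, 12), x = rep(0:1, each = 3))
  expect_equal(fit_ols(y ~ x, d2)$beta, 10)
  # exact line: slope 1 (lm warns about the perfect fit; that is the point)
  d3 <- data.frame(y = 1:6 / 2, x = 1:6 / 2)
  expect_equal(suppressWarnings(fit_ols(y ~ x, d3)$beta), 1,
               tolerance = 1e-12)
})

test_that("predict and residuals are consistent with the fitted model", {
  set.seed(30)
  d <- data.frame(y = rnorm(60), x = rbinom(60, 1, 0.5))
  f <- cqr(y ~ x, d, tau = 0.3)
  expect_equal(unname(fitted(f) + residuals(f)), d$y)
  nd <- data.frame(x = c(0, 1))
  pr <- predict(f, nd)
  expect_equal(unname(pr[2] - pr[1]), unname(coef(f)["x"]))
})

test_that("bootstrap intervals are reproducible and degenerate correctly", {
  # zero noise: interval collapses on the true coefficient
  d0 <- data.frame(x = rep(0:1, each = 25))
  d0$y <- 1 + 2 * d0$x
  ci0 <- bootstrap_ci(y ~ x, d0, estimator = "CQR", tau = 0.5,
                      n_boot = 100, seed = 1)
  expect_equal(as.numeric(ci0), c(2, 2))
  # reproducibility
  set.seed(31)
  d <- data.frame(y = rnorm(200), x = rbinom(200, 1, 0.5))
  ci1 <- bootstrap_ci(y ~ x, d, estimator = "CQR", tau = 0.25,
                      n_boot = 150, seed = 99)
  ci2 <- bootstrap_ci(y ~ x, d, estimator = "CQR", tau = 0.25,
                      n_boot = 150, seed = 99)
  expect_identical(ci1, ci2)
  expect_lt(ci1[["ci_low"]], ci1[["ci_high"]])
  expect_error(bootstrap_ci(y ~ x, d, n_boot = 50, seed = 1), "100")
})

test_that("saturated fits equal the group-quantile oracle at odd sizes", {
  set.seed(32)
  for (rep in 1:10) {
    n0 <- 51; n1 <- 41
    d <- data.frame(y = c(rnorm(n0), 0.5 + 1.5 * rnorm(n1)),
                    x = rep(0:1, c(n0, n1)))
    for (tau in c(0.05, 0.25, 0.5)) {
      expect_equal(unname(coef(cqr(y ~ x, d, tau = tau))["x"]),
                   group_quantile_oracle(d$y, d$x, tau))
    }
  }
})
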