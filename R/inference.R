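# Second-stage inference -----------------------------------------------------

#' Permutation contrast of a tail effect against the median effect
#'
#' Tests whether the exposure effect at quantile `tau` differs from the
#' effect at `tau_ref` (default 0.50, approximate emmetropia). The observed
#' contrast is `delta = beta(tau) - beta(tau_ref)` from fits on the
#' observed data. The null distribution is built by randomly permuting the
#' exposure column while holding the response and covariates fixed — the
#' exchangeable null of no effect at any quantile — and refitting both
#' quantile regressions per permutation. By default the same permuted
#' exposure is used for the `tau` and `tau_ref` fits within a replicate
#' (paired contrast, lower Monte Carlo variance); `paired = FALSE` draws
#' independent permutations for each side.
#'
#' The two-sided p-value is `(1 + #\{|delta*| >= |delta_obs|\}) / (B + 1)`.
#'
#' @param formula model formula; first RHS term = exposure.
#' @param data a data frame.
#' @param tau quantile of interest.
#' @param tau_ref reference quantile (default 0.50).
#' @param n_perm number of permutations B (at least 99).
#' @param seed integer seed.
#' @param paired reuse each permuted exposure for both quantiles.
#' @return an object of class `perm_contrast`: list with `delta_obs`,
#'   `beta_tau`, `beta_ref`, `p`, `n_perm`, `tau`, `tau_ref`, `seed`.
#' @export
permutation_quantile_contrast <- function(formula, data, tau,
                                          tau_ref = 0.5, n_perm = 199,
                                          seed = 1, paired = TRUE) {
  if (tau == tau_ref) stop_invalid("tau must differ from tau_ref")
  if (n_perm < 99) stop_invalid("n_perm must be at least 99")
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  mt <- attr(mf, "terms")
  y <- model.response(mf)
  X <- model.matrix(mt, mf)
  exposure <- exposure_name(formula, data)
  # columns of the design belonging to the exposure (first RHS term)
  ecols <- which(attr(X, "assign") == 1L)
  if (length(unique(X[, ecols[1]])) < 2)
    stop_invalid("no permutation distribution: exposure is constant")
  slope <- function(Xm, t) rq_fit(Xm, y, t)$coefficients[[ecols[1]]]
  beta_tau <- slope(X, tau)
  beta_ref <- slope(X, tau_ref)
  delta_obs <- beta_tau - beta_ref
  n <- nrow(X)
  delta_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Xp <- X
      Xp[, ecols] <- X[sample.int(n), ecols, drop = FALSE]
      d1 <- slope(Xp, tau)
      if (!paired) Xp[, ecols] <- X[sample.int(n), ecols, drop = FALSE]
      d1 - slope(Xp, tau_ref)
    }, numeric(1))
  })
  p <- (1 + sum(abs(delta_null) >= abs(delta_obs))) / (n_perm + 1)
  structure(list(delta_obs = delta_obs, beta_tau = beta_tau,
                 beta_ref = beta_ref, p = p, n_perm = n_perm,
                 tau = tau, tau_ref = tau_ref, seed = seed,
                 exposure = exposure),
            class = "perm_contrast")
}

#' @export
#' @method print perm_contrast
print.perm_contrast <- function(x, digits = 4, ...) {
  cat(sprintf("Permutation contrast for `%s`: beta(%.2f) - beta(%.2f)\n",
              x$exposure, x$tau, x$tau_ref))
  cat(sprintf("  delta = %.*f D  (beta(%.2f) = %.*f, beta(%.2f) = %.*f)\n",
              digits, x$delta_obs, x$tau, digits, x$beta_tau,
              x$tau_ref, digits, x$beta_ref))
  cat(sprintf("  p = %.4g  (%d permutations)\n", x$p, x$n_perm))
  invisible(x)
}

#' Random-effects meta-regression of effect size on age
#'
#' Tests for a linear trend of effect size with age across research-clinic
#' visits: a random-effects meta-regression with age as moderator,
#' method-of-moments (DerSimonian-Laird) between-age heterogeneity
#' variance tau2, inverse-variance weights `1/(se^2 + tau2)`, and a normal
#' reference for the slope test. Fitted through \pkg{metafor}.
#'
#' @param beta per-age effect estimates, diopters.
#' @param se per-age standard errors (positive).
#' @param age ages in years (at least 3 distinct values).
#' @return a data frame row: `slope` (D/year), `se`, `z`, `p`, `tau2`.
#' @examples
#' meta_regression_trend(c(-0.06, -0.10, -0.15, -0.21),
#'                       rep(0.03, 4), c(7, 10, 12, 15))
#' @export
meta_regression_trend <- function(beta, se, age) {
  if (length(beta) < 3) stop_invalid("need at least 3 ages")
  if (any(se <= 0)) stop_invalid("standard errors must be positive")
  if (length(unique(age)) < 3) stop_invalid("need at least 3 distinct ages")
  fit <- metafor::rma(yi = beta, sei = se, mods = ~age,
                      method = "DL", test = "z")
  data.frame(slope = unname(fit$beta["age", 1]),
             se = unname(fit$se[2]),
             z = unname(fit$zval[2]),
             p = unname(fit$pval[2]),
             tau2 = fit$tau2)
}

#' Loess smoothing of a quantile effect profile
#'
#' Local linear regression with tricube weights, evaluated at the same
#' grid of quantile levels, used to display the shape of the effect-size
#' versus quantile relationship (typically an inverted U).
#'
#' @param tau grid of quantile levels (at least 4).
#' @param beta raw effect estimates at each grid point.
#' @param span smoothing span in (0, 1]; fraction of points in each local
#'   neighbourhood.
#' @return data frame `tau`, `beta_raw`, `beta_smooth`.
#' @export
loess_profile <- function(tau, beta, span = 0.75) {
  if (length(tau) < 4) stop_invalid("need at least 4 grid points")
  if (span <= 0 || span > 1) stop_invalid("span must lie in (0, 1]")
  if (span * length(tau) < 2)
    stop_invalid("span too small for local linear fits")
  # each local linear fit needs at least 4 points to be well conditioned
  span <- max(span, min(1, 4 / length(tau)))
  fit <- loess(beta ~ tau, degree = 1, span = span,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  data.frame(tau = tau, beta_raw = beta,
             beta_smooth = predict(fit, data.frame(tau = tau)))
}
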