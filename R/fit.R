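# OLS companion and bootstrap confidence intervals ---------------------------

#' Ordinary least squares effect estimate
#'
#' The "conventional" analysis companion to [cqr()]: a univariate linear
#' model (plus any covariates in the formula) fitted by least squares, with
#' classical standard errors, normal 95% confidence interval and two-sided
#' p-value for the exposure coefficient.
#'
#' @param formula model formula; first RHS term = exposure.
#' @param data a data frame (complete cases of the model variables used).
#' @param level confidence level.
#' @return a one-row data frame: `estimator`, `tau` (NA), `n`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `p`. The fitted `lm` object is attached as
#'   attribute `"fit"`.
#' @export
fit_ols <- function(formula, data, level = 0.95) {
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  fit <- lm(formula, data = as.data.frame(mf))
  exposure <- exposure_name(formula, data)
  i <- exposure_coef(fit, exposure)
  beta <- coef(fit)[[i]]
  se <- sqrt(diag(vcov(fit)))[[i]]
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(estimator = "OLS", tau = NA_real_,
                    n = nrow(mf), beta = beta, se = se,
                    ci_low = beta - z * se, ci_high = beta + z * se,
                    p = 2 * pnorm(-abs(beta / se)))
  attr(out, "fit") <- fit
  out
}

# Case-resampling bootstrap of all coefficients; returns a B x p matrix.
# Degenerate (rank-deficient) resamples are skipped and logged; more than
# 10% skips is an error.
bootstrap_coefs <- function(formula, data, estimator = c("CQR", "OLS"),
                            tau = 0.5, n_boot = 200, seed = 1) {
  estimator <- match.arg(estimator)
  mf <- as.data.frame(model.frame(formula, data,
                                  na.action = stats::na.omit))
  n <- nrow(mf)
  fit_fun <- if (estimator == "CQR") {
    function(d) coef(cqr(formula, d, tau = tau))
  } else {
    function(d) coef(lm(formula, data = d))
  }
  p0 <- length(fit_fun(mf))
  skipped <- 0L
  out <- with_seed(seed, {
    reps <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      cb <- tryCatch(fit_fun(mf[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(cb) || length(cb) != p0 || anyNA(cb)) {
        skipped <- skipped + 1L
        next
      }
      reps[[b]] <- cb
    }
    do.call(rbind, reps)
  })
  if (skipped > 0.10 * n_boot)
    stop_invalid("more than 10% of bootstrap resamples were degenerate (",
                 skipped, "/", n_boot, ")")
  attr(out, "skipped") <- skipped
  out
}

#' Percentile bootstrap confidence interval for the exposure effect
#'
#' Case-resampling percentile bootstrap of the exposure coefficient under
#' either estimator; refits on each resample and takes the empirical
#' `alpha/2` and `1 - alpha/2` quantiles. Deterministic given `seed`.
#'
#' @param formula model formula; first RHS term = exposure.
#' @param data a data frame.
#' @param estimator `"CQR"` or `"OLS"`.
#' @param tau quantile level (CQR only).
#' @param n_boot bootstrap replicates (at least 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return named vector `c(ci_low, ci_high)` with attributes `se`
#'   (bootstrap standard error), `p` (normal-approximation two-sided
#'   p-value) and `skipped` (degenerate resamples).
#' @export
bootstrap_ci <- function(formula, data, estimator = c("CQR", "OLS"),
                         tau = 0.5, n_boot = 200, seed = 1, level = 0.95) {
  estimator <- match.arg(estimator)
  if (n_boot < 100) stop_invalid("n_boot must be at least 100")
  exposure <- exposure_name(formula, data)
  bs <- bootstrap_coefs(formula, data, estimator, tau, n_boot, seed)
  full <- if (estimator == "CQR") coef(cqr(formula, data, tau = tau))
          else coef(lm(formula, data = data))
  i <- exposure_coef(structure(list(coefficients = full), class = "cqr"),
                     exposure)
  vals <- bs[, i]
  alpha <- (1 - level) / 2
  ci <- quantile(vals, probs = c(alpha, 1 - alpha), names = FALSE, type = 1)
  se <- sd(vals)
  p <- if (se > 0) 2 * pnorm(-abs(full[[i]] / se)) else as.numeric(full[[i]] == 0)
  structure(setNames(ci, c("ci_low", "ci_high")),
            se = se, p = p, skipped = attr(bs, "skipped"))
}

#' One-factor effect estimates: OLS plus the full quantile grid
#'
#' The workhorse behind the pipeline's per-factor, per-age analysis: on the
#' complete cases of `response ~ exposure + covariates`, fit OLS and one
#' conditional quantile regression per grid point, with percentile
#' bootstrap intervals for the quantile fits.
#'
#' @param data a coded cohort data frame.
#' @param response,exposure,covariates column names.
#' @param taus quantile grid.
#' @param n_boot bootstrap replicates for CQR intervals (0 to skip).
#' @param seed integer seed.
#' @param level confidence level.
#' @return data frame with one OLS row and one row per quantile level:
#'   `estimator`, `tau`, `n`, `beta`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
effect_estimates <- function(data, response, exposure,
                             covariates = character(),
                             taus = quantile_grid(), n_boot = 200,
                             seed = 1, level = 0.95) {
  f <- reformulate(c(exposure, covariates), response = response)
  cc <- as.data.frame(model.frame(f, data, na.action = stats::na.omit))
  ols <- fit_ols(f, cc, level = level)
  attr(ols, "fit") <- NULL
  grid <- cqr_grid(f, cc, taus = taus, n_boot = n_boot, level = level,
                   seed = seed)
  eff <- grid$effects
  cqr_rows <- data.frame(estimator = "CQR", tau = eff$tau, n = eff$n,
                         beta = eff$beta, se = NA_real_,
                         ci_low = eff$ci_low, ci_high = eff$ci_high,
                         p = eff$p)
  rbind(ols, cqr_rows)
}
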