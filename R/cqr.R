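# Conditional quantile regression --------------------------------------------

#' Pinball (check) loss
#'
#' The asymmetric piecewise-linear loss whose minimiser is the tau-th
#' quantile: `rho_tau(u) = u * (tau - 1\{u < 0\})`.
#'
#' @param residuals numeric vector of residuals, diopters.
#' @param tau quantile level in (0, 1).
#' @return the summed loss (nonnegative; zero iff all residuals are zero).
#' @examples
#' pinball_loss(c(1, -1), 0.5)   # 1
#' @export
pinball_loss <- function(residuals, tau) {
  if (length(tau) != 1 || tau <= 0 || tau >= 1)
    stop_invalid("tau must lie in (0, 1)")
  sum(residuals * (tau - (residuals < 0)))
}

# Check the design for full column rank; report offending columns.
check_full_rank <- function(X) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop_invalid("design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Vertex polish: an optimal basic solution interpolates p observations.
# Try the p observations with the smallest absolute interior-point
# residuals; accept the refit only if it does not increase the loss.
polish_vertex <- function(X, y, tau, coef, resid) {
  p <- ncol(X)
  loss0 <- pinball_loss(y - X %*% coef, tau)
  idx <- order(abs(resid))[seq_len(min(p * 2L, nrow(X)))]
  best <- list(coef = coef, loss = loss0)
  cand <- if (p <= length(idx)) idx[seq_len(p)] else idx
  Xi <- X[cand, , drop = FALSE]
  b <- tryCatch(solve(Xi, y[cand]), error = function(e) NULL)
  if (!is.null(b)) {
    l <- pinball_loss(y - X %*% b, tau)
    if (l <= best$loss + 1e-9 * (1 + abs(best$loss)))
      best <- list(coef = drop(b), loss = l)
  }
  best
}

# Low-level fit on a numeric design matrix.
rq_fit <- function(X, y, tau, eps = 1e-10, max_it = 200) {
  if (length(tau) != 1 || tau <= 0 || tau >= 1)
    stop_invalid("tau must lie in (0, 1)")
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X))
    stop_invalid("need more complete cases than parameters")
  check_full_rank(X)
  fit <- rqfn_cpp(X, y, tau, eps = eps, max_it = max_it)
  pol <- polish_vertex(X, y, tau, drop(fit$coefficients),
                       drop(fit$residuals))
  coef <- setNames(pol$coef, colnames(X))
  list(coefficients = coef,
       residuals = drop(y - X %*% pol$coef),
       loss = pol$loss,
       iterations = fit$iterations,
       converged = fit$converged)
}

#' Fit a linear conditional quantile regression
#'
#' Estimates the coefficients minimising the pinball loss
#' `sum_i rho_tau(y_i - x_i'b)` by a Frisch-Newton primal-dual interior
#' point method on the bounded-variables dual linear program, followed by a
#' vertex-polish step that recovers the exact basic solution when it is
#' unique. The fit is deterministic; no step sizes need tuning.
#'
#' @param formula model formula; the first right-hand-side term is treated
#'   as the exposure of interest by downstream helpers.
#' @param data a data frame; rows with missing values in the model
#'   variables are dropped (complete-case analysis).
#' @param tau quantile level in (0, 1).
#' @param ... reserved.
#' @return an object of class `cqr` with `coefficients`, `residuals`,
#'   `fitted.values`, `loss` (achieved pinball loss), `tau`, `n`, and the
#'   model frame metadata needed by [predict.cqr()].
#' @examples
#' d <- data.frame(y = c(0, 1, 2, 10, 11, 12), x = rep(0:1, each = 3))
#' coef(cqr(y ~ x, d, tau = 0.5))   # intercept 1, slope 10
#' @seealso [cqr_grid()] for fits across a grid of quantiles.
#' @export
cqr <- function(formula, data, tau = 0.5, ...) {
  cl <- match.call()
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  mt <- attr(mf, "terms")
  y <- model.response(mf)
  X <- model.matrix(mt, mf)
  fit <- rq_fit(X, y, tau)
  structure(list(coefficients = fit$coefficients,
                 residuals = fit$residuals,
                 fitted.values = drop(y - fit$residuals),
                 loss = fit$loss, tau = tau, n = nrow(X),
                 iterations = fit$iterations,
                 terms = mt, xlevels = stats::.getXlevels(mt, mf),
                 call = cl, formula = formula),
            class = "cqr")
}

#' @export
#' @method print cqr
print.cqr <- function(x, digits = max(3, getOption("digits") - 3), ...) {
  cat("Conditional quantile regression, tau =", format(x$tau), "\n")
  cat("n =", x$n, "  pinball loss =", format(x$loss, digits = digits), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
#' @method coef cqr
coef.cqr <- function(object, ...) object$coefficients

#' @export
#' @method residuals cqr
residuals.cqr <- function(object, ...) object$residuals

#' @export
#' @method fitted cqr
fitted.cqr <- function(object, ...) object$fitted.values

#' Predict conditional quantiles from a fitted cqr model
#'
#' @param object a fitted [cqr()] model.
#' @param newdata data frame of covariate values; the training data's
#'   fitted values are returned when omitted.
#' @param ... ignored.
#' @return predicted tau-th conditional quantiles, diopters.
#' @export
predict.cqr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- delete.response(object$terms)
  mf <- model.frame(tt, newdata, xlev = object$xlevels)
  X <- model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}

#' Summarise a cqr fit with bootstrap confidence intervals
#'
#' Case-resampling percentile bootstrap for all coefficients; with
#' `n_boot = 0` only the point estimates are reported.
#'
#' @param object a fitted [cqr()] model.
#' @param n_boot bootstrap replicates (0 to skip).
#' @param level confidence level.
#' @param seed integer seed for the resampling.
#' @param data the data used in the original fit; required when
#'   `n_boot > 0`.
#' @param ... ignored.
#' @return an object of class `summary.cqr` containing a coefficient table.
#' @export
#' @method summary cqr
summary.cqr <- function(object, n_boot = 0, level = 0.95, seed = 1,
                        data = NULL, ...) {
  tab <- cbind(estimate = object$coefficients)
  if (n_boot > 0) {
    if (is.null(data)) stop_invalid("summary with bootstrap needs `data`")
    bs <- bootstrap_coefs(object$formula, data, estimator = "CQR",
                          tau = object$tau, n_boot = n_boot, seed = seed)
    alpha <- (1 - level) / 2
    ci <- t(apply(bs, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
    se <- apply(bs, 2, sd)
    z <- object$coefficients / se
    tab <- cbind(estimate = object$coefficients, se = se,
                 ci_low = ci[, 1], ci_high = ci[, 2],
                 p = 2 * pnorm(-abs(z)))
  }
  structure(list(tau = object$tau, n = object$n, loss = object$loss,
                 coefficients = tab, n_boot = n_boot, level = level),
            class = "summary.cqr")
}

#' @export
#' @method print summary.cqr
print.summary.cqr <- function(x, digits = 4, ...) {
  cat("Conditional quantile regression, tau =", format(x$tau),
      " (n =", x$n, ")\n")
  if (x$n_boot > 0)
    cat(sprintf("%d bootstrap replicates, %.0f%% percentile intervals\n",
                x$n_boot, 100 * x$level))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Default 19-point quantile grid
#'
#' Quantile levels 0.05, 0.10, ..., 0.95 — the grid used to profile risk
#' factor effects across the refractive error distribution.
#'
#' @return numeric vector of 19 quantile levels.
#' @export
quantile_grid <- function() seq(0.05, 0.95, by = 0.05)

#' Fit conditional quantile regressions across a quantile grid
#'
#' One [cqr()] fit per quantile level, all on the identical complete-case
#' sample, with the exposure (first right-hand-side term) coefficient
#' extracted as the effect of interest.
#'
#' @param formula model formula; first RHS term = exposure.
#' @param data a data frame.
#' @param taus quantile levels (default [quantile_grid()]).
#' @param n_boot bootstrap replicates for per-tau percentile confidence
#'   intervals (0 to skip).
#' @param level confidence level for the intervals.
#' @param seed integer seed used when `n_boot > 0`.
#' @return an object of class `cqr_grid`: a data frame of per-tau effects
#'   (`tau`, `beta`, `ci_low`, `ci_high`, `p`, `n`) plus the list of fits.
#' @export
cqr_grid <- function(formula, data, taus = quantile_grid(), n_boot = 0,
                     level = 0.95, seed = 1) {
  if (is.unsorted(taus, strictly = TRUE))
    stop_invalid("taus must be strictly increasing")
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  cc <- as.data.frame(mf)
  exposure <- exposure_name(formula, data)
  fits <- lapply(taus, function(t) cqr(formula, cc, tau = t))
  beta <- vapply(fits, function(f) coef(f)[[exposure_coef(f, exposure)]],
                 numeric(1))
  out <- data.frame(tau = taus, beta = beta, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_,
                    n = vapply(fits, `[[`, numeric(1), "n"))
  if (n_boot > 0) {
    for (i in seq_along(taus)) {
      ci <- bootstrap_ci(formula, cc, estimator = "CQR", tau = taus[i],
                         n_boot = n_boot, seed = child_seed(seed, taus[i]),
                         level = level)
      out$ci_low[i] <- ci["ci_low"]; out$ci_high[i] <- ci["ci_high"]
      out$p[i] <- attr(ci, "p")
    }
  }
  structure(list(effects = out, fits = fits, exposure = exposure,
                 formula = formula),
            class = "cqr_grid")
}

# name of the exposure variable (first RHS term) and of its coefficient
exposure_name <- function(formula, data) {
  attr(terms(formula, data = data), "term.labels")[1]
}
exposure_coef <- function(fit, exposure) {
  nm <- names(coef(fit))
  hit <- which(nm == exposure)
  if (length(hit) == 0) hit <- grep(paste0("^", exposure), nm)[1]
  if (is.na(hit) || length(hit) == 0)
    stop_invalid("cannot locate exposure coefficient ", exposure)
  hit
}

#' @export
#' @method print cqr_grid
print.cqr_grid <- function(x, digits = 4, ...) {
  cat("Quantile effect profile for exposure `", x$exposure, "` (",
      nrow(x$effects), " quantile levels)\n", sep = "")
  print(round(as.data.frame(x$effects), digits))
  invisible(x)
}

#' @export
#' @method coef cqr_grid
coef.cqr_grid <- function(object, ...) {
  setNames(object$effects$beta, object$effects$tau)
}

#' Plot a quantile effect profile
#'
#' Effect size (diopters) against quantile level, with bootstrap intervals
#' when present and an optional loess smooth.
#'
#' @param x a [cqr_grid()] object.
#' @param smooth add a loess smooth of the profile.
#' @param span loess span.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.cqr_grid <- function(x, smooth = TRUE, span = 0.75, ...) {
  e <- x$effects
  ylim <- range(c(e$beta, e$ci_low, e$ci_high), na.rm = TRUE)
  graphics::plot(e$tau, e$beta, pch = 16, ylim = ylim,
                 xlab = "quantile of refractive error",
                 ylab = "effect size (D)", ...)
  if (!all(is.na(e$ci_low)))
    graphics::arrows(e$tau, e$ci_low, e$tau, e$ci_high,
                     angle = 90, code = 3, length = 0.02)
  graphics::abline(h = 0, lty = 3)
  if (smooth && nrow(e) >= 4) {
    sm <- loess_profile(e$tau, e$beta, span = span)
    graphics::lines(sm$tau, sm$beta_smooth, col = 2)
  }
  invisible(x)
}

#' Difference of group sample quantiles (saturated-model oracle)
#'
#' For a single binary covariate with no others, the quantile regression
#' slope equals the difference of per-group sample quantiles whenever the
#' group quantile is uniquely attained. The order-statistic convention
#' `y_(ceil(n * tau))` matches the check-loss minimiser.
#'
#' @param y response vector.
#' @param x binary 0/1 group indicator.
#' @param tau quantile level in (0, 1).
#' @return the slope `Q_tau(y | x = 1) - Q_tau(y | x = 0)`.
#' @export
group_quantile_oracle <- function(y, x, tau) {
  if (length(tau) != 1 || tau <= 0 || tau >= 1)
    stop_invalid("tau must lie in (0, 1)")
  q_of <- function(v) {
    if (length(v) == 0) stop_invalid("empty group")
    sort(v)[max(1L, ceiling(length(v) * tau))]
  }
  q_of(y[x == 1]) - q_of(y[x == 0])
}
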