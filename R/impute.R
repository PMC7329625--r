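# Multiple imputation by chained equations and Rubin pooling -----------------

# Bayesian-draw logistic imputation of a binary column given predictors:
# fit on the observed rows, draw coefficients from the approximate
# posterior N(betahat, vcov), draw imputations Bernoulli(plogis(X beta*)).
impute_logreg <- function(y, X_obs, X_mis) {
  df <- data.frame(.y = y, X_obs)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  bh <- coef(fit)
  V <- vcov(fit)
  ok <- !is.na(bh)
  bstar <- bh
  bstar[ok] <- bh[ok] + drop(t(chol(V[ok, ok, drop = FALSE] +
                                      diag(1e-10, sum(ok)))) %*% rnorm(sum(ok)))
  Xm <- model.matrix(~., data = X_mis)
  Xm <- Xm[, names(bstar)[ok], drop = FALSE]
  p <- plogis(drop(Xm %*% bstar[ok]))
  rbinom(length(p), 1, p)
}

# Predictive mean matching (k donors) with a Bayesian linear-model draw.
impute_pmm <- function(y, X_obs, X_mis, k = 5L) {
  df <- data.frame(.y = y, X_obs)
  fit <- lm(.y ~ ., data = df)
  bh <- coef(fit); ok <- !is.na(bh)
  res <- residuals(fit)
  df_res <- max(1L, fit$df.residual)
  sigma2 <- sum(res^2) / rchisq(1, df_res)
  XtX <- crossprod(model.matrix(fit)[, ok, drop = FALSE])
  bstar <- bh
  bstar[ok] <- bh[ok] +
    drop(t(chol(sigma2 * solve(XtX + diag(1e-10, sum(ok))))) %*%
           rnorm(sum(ok)))
  Xo <- model.matrix(~., data = X_obs)[, names(bh)[ok], drop = FALSE]
  Xm <- model.matrix(~., data = X_mis)[, names(bh)[ok], drop = FALSE]
  yhat_obs <- drop(Xo %*% bh[ok])
  yhat_mis <- drop(Xm %*% bstar[ok])
  vapply(yhat_mis, function(v) {
    donors <- order(abs(yhat_obs - v))[seq_len(min(k, length(yhat_obs)))]
    y[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Fills missing values column by column: each incomplete column is
#' imputed from a model on all other analysis columns (including the
#' response, per standard imputation guidance), sweeping the columns
#' `n_iter` times, and the whole procedure is repeated to produce `m`
#' completed data sets. Binary columns use Bayesian logistic draws,
#' continuous columns predictive mean matching with `k = 5` donors, and
#' `"sample"` draws from the observed values ignoring predictors. Observed
#' cells are never modified.
#'
#' @param table a cohort data frame.
#' @param m number of completed data sets (at least 2).
#' @param n_iter chained-equation sweeps per data set.
#' @param methods named per-column methods among `"logreg"`, `"pmm"`,
#'   `"sample"`; defaults chosen from the column type (binary -> logreg,
#'   numeric -> pmm).
#' @param predictors columns used as predictors (default: all numeric or
#'   binary columns except identifiers).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a list of `m` completed data frames, classed `mice_result`,
#'   with the imputation `methods` attached as an attribute.
#' @export
mice_impute <- function(table, m = 20, n_iter = 10, methods = NULL,
                        predictors = NULL, seed = 1) {
  if (m < 2) stop_invalid("m must be at least 2")
  if (n_iter < 1) stop_invalid("n_iter must be at least 1")
  drop_cols <- c("subject_id", "cohort")
  if (is.null(predictors))
    predictors <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          drop_cols)
  incomplete <- names(table)[vapply(table, anyNA, logical(1))]
  incomplete <- intersect(incomplete, predictors)
  fully_missing <- incomplete[vapply(incomplete, function(cl)
    all(is.na(table[[cl]])), logical(1))]
  if (length(fully_missing))
    stop_invalid("column(s) fully missing: ",
                 paste(fully_missing, collapse = ", "))
  if (length(incomplete) > 0 &&
      !any(vapply(predictors, function(cl) !anyNA(table[[cl]]), logical(1))))
    stop_invalid("need at least one fully observed predictor column")
  if (is.null(methods)) {
    methods <- vapply(incomplete, function(cl)
      if (is_binary01(table[[cl]])) "logreg" else "pmm", character(1))
  } else {
    miss_m <- setdiff(incomplete, names(methods))
    if (length(miss_m))
      stop_invalid("no imputation method declared for: ",
                   paste(miss_m, collapse = ", "))
    methods <- unlist(methods)[incomplete]
  }
  # impute columns in increasing order of missingness
  n_mis <- vapply(incomplete, function(cl) sum(is.na(table[[cl]])),
                  numeric(1))
  ord <- incomplete[order(n_mis)]
  completed <- with_seed(seed, {
    lapply(seq_len(m), function(im) {
      cur <- table
      # initial fill: sample from observed values
      for (cl in ord) {
        mis <- is.na(cur[[cl]])
        obs_vals <- cur[[cl]][!mis]
        cur[[cl]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
      }
      if (length(ord) == 0) return(cur)
      for (it in seq_len(n_iter)) {
        for (cl in ord) {
          mis <- is.na(table[[cl]])
          if (!any(mis)) next
          preds <- setdiff(predictors, cl)
          X <- cur[preds]
          y_obs <- table[[cl]][!mis]
          filled <- switch(methods[[cl]],
            logreg = impute_logreg(y_obs, X[!mis, , drop = FALSE],
                                   X[mis, , drop = FALSE]),
            pmm = impute_pmm(y_obs, X[!mis, , drop = FALSE],
                             X[mis, , drop = FALSE]),
            sample = sample(y_obs, sum(mis), replace = TRUE),
            stop_invalid("unknown method: ", methods[[cl]]))
          cur[[cl]][mis] <- filled
        }
      }
      cur
    })
  })
  structure(completed, class = c("mice_result", "list"), methods = methods)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines `m` per-imputation estimates and standard errors:
#' `beta_pooled = mean(beta)`, within-variance `W = mean(se^2)`,
#' between-variance `B = var(beta)`, total variance `W + (1 + 1/m) B`,
#' small-sample degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2` and a two-sided t p-value
#' (normal when `B = 0`).
#'
#' @param beta per-imputation estimates.
#' @param se per-imputation standard errors (positive).
#' @return a one-row data frame: `beta`, `se`, `W`, `B`, `df`, `p`, `m`.
#' @examples
#' pool_rubin(c(0.9, 1.1), c(0.1, 0.1))   # se = sqrt(0.01 + 1.5 * 0.02)
#' @export
pool_rubin <- function(beta, se) {
  m <- length(beta)
  if (m < 2) stop_invalid("need at least 2 imputations")
  if (length(se) != m || any(se <= 0))
    stop_invalid("need one positive se per estimate")
  W <- mean(se^2)
  B <- var(beta)
  Tv <- W + (1 + 1 / m) * B
  pooled <- mean(beta)
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    p <- 2 * pt(-abs(pooled / sqrt(Tv)), df = df)
  } else {
    df <- Inf
    p <- 2 * pnorm(-abs(pooled / sqrt(Tv)))
  }
  data.frame(beta = pooled, se = sqrt(Tv), W = W, B = B, df = df,
             p = p, m = m)
}

#' Pooled effect estimate from multiply imputed data
#'
#' Runs the chosen estimator on each completed data set and pools with
#' Rubin's rules. OLS uses classical standard errors; quantile regression
#' uses a case-resampling bootstrap standard error within each imputation.
#'
#' @param completed a `mice_result` (list of completed data frames).
#' @param response,exposure,covariates column names.
#' @param estimator `"OLS"` or `"CQR"`.
#' @param tau quantile level (CQR only).
#' @param n_boot bootstrap replicates per imputation for the CQR standard
#'   error.
#' @param seed integer seed.
#' @return a one-row data frame as from [pool_rubin()], plus `estimator`
#'   and `tau` columns.
#' @export
pooled_effect <- function(completed, response, exposure,
                          covariates = character(),
                          estimator = c("OLS", "CQR"), tau = 0.5,
                          n_boot = 100, seed = 1) {
  estimator <- match.arg(estimator)
  f <- reformulate(c(exposure, covariates), response = response)
  res <- lapply(seq_along(completed), function(k) {
    d <- completed[[k]]
    if (estimator == "OLS") {
      est <- fit_ols(f, d)
      c(est$beta, est$se)
    } else {
      fit <- cqr(f, d, tau = tau)
      b <- coef(fit)[[exposure_coef(fit, exposure)]]
      ci <- bootstrap_ci(f, d, estimator = "CQR", tau = tau,
                         n_boot = n_boot, seed = child_seed(seed, k))
      c(b, attr(ci, "se"))
    }
  })
  mat <- do.call(rbind, res)
  out <- pool_rubin(mat[, 1], mat[, 2])
  out$estimator <- paste0(estimator, "-MI")
  out$tau <- if (estimator == "CQR") tau else NA_real_
  out
}
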