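# Analysis pipeline ----------------------------------------------------------

#' Rank-based quantile bin assignment
#'
#' Ranks subjects by the response and divides them into `k` bins whose
#' sizes differ by at most one, ties broken by stable original order —
#' the binning used to display the refractive error distribution by
#' quantile.
#'
#' @param y numeric vector.
#' @param k number of bins (at least 2, at most `length(y)`).
#' @return integer bin labels in `1:k`, aligned with `y`.
#' @export
quantile_bins <- function(y, k) {
  n <- length(y)
  if (k < 2) stop_invalid("k must be at least 2")
  if (k > n) stop_invalid("k must not exceed the number of subjects")
  ord <- order(y)                     # stable: ties keep original order
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(k), times = sizes)
  bins
}

#' Configure a full risk-factor analysis
#'
#' Bundles everything [run_analysis()] needs: the input (either a
#' [sim_config()] to simulate from, or a cohort TSV path), the factors and
#' covariates to analyse, the quantile grid, Monte Carlo sizes, and the
#' imputation branch.
#'
#' @param input a [sim_config()] or a path to a cohort TSV.
#' @param factors character vector of binary risk-factor columns; default
#'   (for simulated input) all configured factors.
#' @param response response column (diopters).
#' @param covariates covariate columns included in every model (e.g. an
#'   ethnicity dummy); default none.
#' @param taus quantile grid.
#' @param n_boot bootstrap replicates for CQR confidence intervals.
#' @param contrast_taus quantiles contrasted against `tau_ref` by
#'   permutation.
#' @param tau_ref reference quantile for contrasts.
#' @param n_perm permutations per contrast.
#' @param impute run the multiple-imputation sensitivity branch.
#' @param m,n_iter imputation parameters (see [mice_impute()]).
#' @param seed integer seed governing every stochastic stage.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(input, factors = NULL,
                            response = "refractive_error",
                            covariates = character(),
                            taus = quantile_grid(), n_boot = 200,
                            contrast_taus = 0.05, tau_ref = 0.5,
                            n_perm = 199, impute = FALSE, m = 20,
                            n_iter = 10, seed) {
  if (missing(seed)) stop_invalid("a seed is mandatory")
  if (inherits(input, "sim_config")) {
    if (is.null(factors))
      factors <- vapply(input$factors, `[[`, character(1), "name")
  } else if (is.character(input)) {
    if (!file.exists(input)) stop_invalid("input file not found: ", input)
    if (is.null(factors)) stop_invalid("factors must be named for file input")
  } else stop_invalid("input must be a sim_config or a file path")
  structure(list(input = input, factors = factors, response = response,
                 covariates = covariates, taus = taus, n_boot = n_boot,
                 contrast_taus = contrast_taus, tau_ref = tau_ref,
                 n_perm = n_perm, impute = impute, m = m, n_iter = n_iter,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Hash of the analysis-relevant configuration fields
#'
#' MD5 of the canonical deparse of the configuration; changes iff an
#' analysis-relevant field changes. Recorded in the run log so outputs are
#' traceable to the configuration that produced them.
#'
#' @param config an [analysis_config()].
#' @return a hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(lapply(unclass(config), function(x)
    if (inherits(x, "sim_config")) sim_config_to_list(x) else x)),
    collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Demographic summary of a coded cohort table
#'
#' Per age group: sample size, sex split, mean refractive error with its
#' 95% t-interval, and per-factor low/high/missing counts and percentages.
#'
#' @param table a coded cohort data frame.
#' @param factors binary factor columns to tabulate.
#' @param response response column.
#' @return a data frame with one row per age group x factor.
#' @export
summarize_demographics <- function(table, factors = NULL,
                                   response = "refractive_error") {
  if (is.null(factors))
    factors <- setdiff(names(table)[vapply(table, is_binary01, logical(1))],
                       c("sex", "age_group"))
  ages <- sort(unique(table$age_group))
  rows <- list()
  for (age in ages) {
    sub <- table[table$age_group == age, , drop = FALSE]
    n <- nrow(sub)
    y <- sub[[response]]
    ybar <- mean(y, na.rm = TRUE)
    yse <- sd(y, na.rm = TRUE) / sqrt(sum(!is.na(y)))
    tq <- stats::qt(0.975, df = max(1, sum(!is.na(y)) - 1))
    for (fc in factors) {
      x <- sub[[fc]]
      lo <- sum(x == 0, na.rm = TRUE)
      hi <- sum(x == 1, na.rm = TRUE)
      mis <- sum(is.na(x))
      rows[[length(rows) + 1L]] <- data.frame(
        age_group = age, n = n,
        n_female = sum(sub$sex == 1, na.rm = TRUE),
        mean_re = ybar, re_ci_low = ybar - tq * yse,
        re_ci_high = ybar + tq * yse,
        factor = fc, n_low = lo, n_high = hi, n_missing = mis,
        pct_low = 100 * lo / n, pct_high = 100 * hi / n,
        pct_missing = 100 * mis / n)
    }
  }
  do.call(rbind, rows)
}

#' Run the full risk-factor analysis
#'
#' For each factor and age group, on the factor's complete cases: an OLS
#' effect estimate and one conditional quantile regression per grid point
#' (with percentile bootstrap intervals); permutation contrasts of the
#' configured tail quantiles against the median; a random-effects
#' meta-regression age trend per factor and estimator when at least three
#' age groups are available; loess-smoothed effect profiles; a demographic
#' summary; and, optionally, a multiple-imputation sensitivity branch.
#' Every stage derives its seed deterministically from the configuration
#' seed, so a rerun with the same configuration is byte-identical.
#'
#' @param config an [analysis_config()].
#' @return an object of class `report_bundle`: list of data frames
#'   `estimates`, `contrasts`, `trends`, `profiles`, `demographics`, plus
#'   `log` (character) and `config_hash`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("config hash: ", config_hash(config))
  table <- if (inherits(config$input, "sim_config")) {
    note("simulating cohort: n = ", config$input$n_subjects)
    simulate_cohort(config$input)
  } else {
    note("reading cohort from ", config$input)
    read_cohort(config$input)
  }
  ages <- sort(unique(table$age_group))
  estimates <- list(); contrasts <- list(); trends <- list()
  profiles <- list()
  for (fc in config$factors) {
    if (!fc %in% names(table)) stop_invalid("factor column missing: ", fc)
    for (age in ages) {
      sub <- table[table$age_group == age, , drop = FALSE]
      vars <- c(config$response, fc, config$covariates)
      cc <- sub[complete.cases(sub[vars]), vars, drop = FALSE]
      if (length(unique(cc[[fc]])) < 2) {
        note("skipped ", fc, " at age ", age,
             ": fewer than 2 exposure levels after coding")
        next
      }
      note("fit ", fc, " age ", age, ": n = ", nrow(cc), " (dropped ",
           nrow(sub) - nrow(cc), ")")
      est <- effect_estimates(cc, config$response, fc, config$covariates,
                              taus = config$taus, n_boot = config$n_boot,
                              seed = child_seed(config$seed,
                                                paste0("boot", fc, age)))
      est <- cbind(factor = fc, age_group = age, est)
      estimates[[length(estimates) + 1L]] <- est
      f <- reformulate(c(fc, config$covariates),
                       response = config$response)
      for (ct in config$contrast_taus) {
        pc <- permutation_quantile_contrast(
          f, cc, tau = ct, tau_ref = config$tau_ref,
          n_perm = config$n_perm,
          seed = child_seed(config$seed, paste0("perm", fc, age, ct)))
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          factor = fc, age_group = age, tau = ct,
          tau_ref = config$tau_ref, beta_tau = pc$beta_tau,
          beta_ref = pc$beta_ref, delta = pc$delta_obs, p = pc$p,
          n_perm = pc$n_perm)
      }
      cq <- est[est$estimator == "CQR", ]
      if (nrow(cq) >= 4) {
        sm <- loess_profile(cq$tau, cq$beta)
        profiles[[length(profiles) + 1L]] <- data.frame(
          factor = fc, age_group = age, sm)
      }
    }
  }
  estimates <- do.call(rbind, estimates)
  if (is.null(estimates) || nrow(estimates) == 0)
    stop_invalid("empty output: no factor could be analysed")
  if (length(ages) >= 3) {
    for (fc in unique(estimates$factor)) {
      ef <- estimates[estimates$factor == fc, ]
      for (est_lab in c("OLS", paste0("CQR@", config$taus))) {
        if (est_lab == "OLS") {
          rows <- ef[ef$estimator == "OLS", ]
        } else {
          t0 <- as.numeric(sub("CQR@", "", est_lab))
          rows <- ef[ef$estimator == "CQR" & ef$tau == t0, ]
        }
        se <- if (est_lab == "OLS") rows$se
              else (rows$ci_high - rows$ci_low) / (2 * qnorm(0.975))
        if (nrow(rows) < 3 || any(!is.finite(se)) || any(se <= 0)) next
        tr <- meta_regression_trend(rows$beta, se, rows$age_group)
        trends[[length(trends) + 1L]] <- cbind(
          factor = fc, estimator = est_lab, tr)
      }
    }
  }
  bundle <- list(estimates = estimates,
                 contrasts = do.call(rbind, contrasts),
                 trends = if (length(trends)) do.call(rbind, trends),
                 profiles = do.call(rbind, profiles),
                 demographics = summarize_demographics(
                   table, config$factors, config$response),
                 log = log, config_hash = config_hash(config))
  if (config$impute) {
    completed <- mice_impute(table, m = config$m, n_iter = config$n_iter,
                             seed = child_seed(config$seed, "mice"))
    mi <- list()
    for (fc in config$factors) for (age in ages) {
      sub_idx <- lapply(completed, function(d)
        d[d$age_group == age, , drop = FALSE])
      for (est in c("OLS", "CQR")) {
        pe <- pooled_effect(sub_idx, config$response, fc,
                            config$covariates, estimator = est,
                            tau = config$tau_ref,
                            seed = child_seed(config$seed,
                                              paste0("mi", fc, age, est)))
        mi[[length(mi) + 1L]] <- cbind(factor = fc, age_group = age, pe)
      }
    }
    bundle$mi_estimates <- do.call(rbind, mi)
  }
  structure(bundle, class = "report_bundle")
}

#' @export
#' @method print report_bundle
print.report_bundle <- function(x, ...) {
  cat("Risk factor analysis report\n")
  cat("  estimates:  ", nrow(x$estimates), " rows (",
      length(unique(x$estimates$factor)), " factors x ",
      length(unique(x$estimates$age_group)), " ages)\n", sep = "")
  if (!is.null(x$contrasts))
    cat("  contrasts:  ", nrow(x$contrasts), " rows\n", sep = "")
  if (!is.null(x$trends))
    cat("  trends:     ", nrow(x$trends), " rows\n", sep = "")
  if (!is.null(x$mi_estimates))
    cat("  MI branch:  ", nrow(x$mi_estimates), " rows\n", sep = "")
  cat("  config hash ", x$config_hash, "\n", sep = "")
  invisible(x)
}

#' Write a report bundle to TSV files
#'
#' Writes `estimates.tsv`, `contrasts.tsv`, `trends.tsv`, `profiles.tsv`,
#' `demographics.tsv` (and `mi_estimates.tsv` when present) plus `run.log`
#' into `dir`.
#'
#' @param bundle a `report_bundle` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("estimates", "contrasts", "trends", "profiles",
               "demographics", "mi_estimates")) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- bundle[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 10))
    write.table(df, p, sep = "\t", quote = FALSE, na = "",
                row.names = FALSE)
    paths <- c(paths, p)
  }
  lg <- file.path(dir, "run.log")
  writeLines(bundle$log, lg)
  invisible(c(paths, lg))
}
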