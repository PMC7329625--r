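# Synthetic cohort generator -------------------------------------------------
#
# Location-scale data generating process with known quantile-specific risk
# factor effects:
#
#   Y = mu0 + sum_j beta_j X_j + sigma0 * exp(sum_j gamma_j X_j) * eps,
#
# with E[eps] = 0, Var[eps] = 1.  For a single binary factor the true
# conditional quantile effect at tau is
#
#   Q_tau(Y | X = 1) - Q_tau(Y | X = 0)
#     = beta + sigma0 * (exp(gamma) - 1) * F_eps^{-1}(tau),
#
# so a factor with gamma > 0 produces effects that are amplified in the
# tails of the refractive error distribution and vanish toward the quantile
# where F_eps^{-1} = 0, mimicking the tail-amplified pattern seen in real
# childhood cohorts.  Effects can grow linearly with age.

#' Specify a binary risk factor for the synthetic cohort
#'
#' @param name column name of the factor.
#' @param prevalence exposure probability in (0, 1).
#' @param beta location shift in diopters when exposed.
#' @param gamma log-scale shift when exposed (the residual scale is
#'   multiplied by `exp(gamma)` for exposed subjects).
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, prevalence, beta = 0, gamma = 0) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(prevalence > 0 && prevalence < 1))
    stop_invalid("prevalence must lie in (0, 1)")
  structure(list(name = name, prevalence = prevalence,
                 beta = beta, gamma = gamma),
            class = "factor_spec")
}

#' Configure the synthetic cohort data generating process
#'
#' @param n_subjects number of subjects (each contributes one row per age
#'   group).
#' @param age_groups integer ages in years at which refraction is measured.
#' @param factors list of [factor_spec()] objects.
#' @param mu0 baseline mean spherical equivalent in diopters.
#' @param sigma0 baseline residual scale in diopters; must be positive.
#' @param error_shape `"skew-normal"` (default) for a left-skewed
#'   standardised error emulating the myopic tail, or `"normal"`.
#' @param alpha skew-normal shape parameter (ignored for `"normal"`).
#' @param age_slope named numeric vector: per-factor fractional increase of
#'   both `beta` and `gamma` per year beyond the youngest age group.
#'   Factors not named get slope 0.
#' @param factor_corr optional exchangeable correlation in (0, 1) between
#'   the latent variables generating the exposures (Gaussian copula
#'   thresholding).  Correlated exposures have no closed-form quantile
#'   effects.
#' @param missing_rates named per-column missingness probabilities in
#'   `[0, 1)` applied by [simulate_cohort()] after generation.
#' @param mechanism `"MCAR"` or `"MAR"` for the injected missingness.
#' @param mar_condition fully observed column (e.g. `"sex"`) that drives
#'   MAR missingness.
#' @param mar_ratio ratio of missingness odds-free rates between the two
#'   levels of `mar_condition` (level 1 relative to level 0).
#' @param seed integer seed; mandatory for reproducibility.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       age_groups = c(7L, 10L, 12L, 15L),
                       factors = list(),
                       mu0 = 0.1,
                       sigma0 = 1.3,
                       error_shape = c("skew-normal", "normal"),
                       alpha = -4,
                       age_slope = NULL,
                       factor_corr = 0,
                       missing_rates = NULL,
                       mechanism = c("MCAR", "MAR"),
                       mar_condition = "sex",
                       mar_ratio = 2,
                       seed) {
  error_shape <- match.arg(error_shape)
  mechanism <- match.arg(mechanism)
  if (missing(seed)) stop_invalid("a seed is mandatory")
  if (n_subjects < 2) stop_invalid("n_subjects must be at least 2")
  if (sigma0 <= 0) stop_invalid("sigma0 must be positive")
  if (!is.null(missing_rates)) {
    if (is.null(names(missing_rates)) || any(names(missing_rates) == ""))
      stop_invalid("missing_rates must be a named vector")
    if (any(missing_rates < 0 | missing_rates >= 1))
      stop_invalid("missing rates must lie in [0, 1)")
  }
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  for (f in factors) stopifnot(inherits(f, "factor_spec"))
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(fnames)) stop_invalid("duplicate factor names")
  slope <- setNames(rep(0, length(fnames)), fnames)
  if (!is.null(age_slope)) slope[names(age_slope)] <- age_slope
  structure(list(n_subjects = as.integer(n_subjects),
                 age_groups = sort(as.integer(age_groups)),
                 factors = factors, mu0 = mu0, sigma0 = sigma0,
                 error_shape = error_shape, alpha = alpha,
                 age_slope = slope, factor_corr = factor_corr,
                 missing_rates = missing_rates, mechanism = mechanism,
                 mar_condition = mar_condition, mar_ratio = mar_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# effect multiplier at a given age: effects grow linearly from the
# youngest age group
age_multiplier <- function(config, factor_name, age) {
  1 + config$age_slope[[factor_name]] * (age - min(config$age_groups))
}

#' Simulate a cohort table with known quantile-specific effects
#'
#' Generates one row per subject per age group under the location-scale
#' model described in the package vignette.  Exposures are Bernoulli with
#' the configured prevalences (optionally correlated through a Gaussian
#' copula); refraction at different ages is generated independently given
#' the exposures.  If `genotypes` is supplied, the centred polygenic score
#' is added to the location and a binarised `genetic_risk` column
#' (1 = below-average score) is included.
#'
#' @param config a [sim_config()] object.
#' @param genotypes optional [genotype_panel] from [simulate_genotypes()]
#'   whose subjects are recycled to `n_subjects`.
#' @return a `data.frame` (cohort table) with columns `subject_id`,
#'   `age_group`, `sex`, one column per factor, and `refractive_error`
#'   (diopters).  Missingness configured in `config` is injected before
#'   return.
#' @export
simulate_cohort <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  fnames <- vapply(config$factors, `[[`, character(1), "name")
  with_seed(config$seed, {
    sex <- rbinom(n, 1, 0.5)
    k <- length(config$factors)
    if (k > 0) {
      if (config$factor_corr > 0) {
        rho <- config$factor_corr
        z0 <- rnorm(n)
        lat <- sapply(seq_len(k), function(j)
          sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n))
        expo <- sapply(seq_len(k), function(j)
          as.integer(lat[, j] < qnorm(config$factors[[j]]$prevalence)))
      } else {
        expo <- sapply(seq_len(k), function(j)
          rbinom(n, 1, config$factors[[j]]$prevalence))
      }
      expo <- matrix(expo, nrow = n,
                     dimnames = list(NULL, fnames))
    } else {
      expo <- matrix(numeric(0), nrow = n, ncol = 0)
    }
    prs_shift <- 0
    genetic_risk <- NULL
    if (!is.null(genotypes)) {
      score <- compute_prs(genotypes)
      score <- rep_len(score, n)
      prs_shift <- score - mean(score)
      genetic_risk <- as.integer(prs_shift < 0)
    }
    out <- lapply(config$age_groups, function(age) {
      loc <- rep(config$mu0, n) + prs_shift
      logscale <- rep(0, n)
      for (j in seq_len(k)) {
        f <- config$factors[[j]]
        m <- age_multiplier(config, f$name, age)
        loc <- loc + m * f$beta * expo[, j]
        logscale <- logscale + m * f$gamma * expo[, j]
      }
      eps <- if (config$error_shape == "normal") rnorm(n)
             else rskewnorm_std(n, config$alpha)
      y <- loc + config$sigma0 * exp(logscale) * eps
      df <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                       age_group = age, sex = sex,
                       check.names = FALSE, stringsAsFactors = FALSE)
      if (k > 0) df <- cbind(df, as.data.frame(expo))
      if (!is.null(genetic_risk)) df$genetic_risk <- genetic_risk
      df$refractive_error <- y
      df
    })
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    if (!is.null(config$missing_rates)) {
      tab <- inject_missingness(tab, rates = config$missing_rates,
                                mechanism = config$mechanism,
                                condition_on = config$mar_condition,
                                mar_ratio = config$mar_ratio,
                                seed = child_seed(config$seed, "missing"))
    }
    tab
  })
}

#' Closed-form true quantile effect of a single binary factor
#'
#' For a factor with location shift `beta` and log-scale shift `gamma` in
#' the synthetic location-scale model, the true conditional quantile effect
#' is `beta + sigma0 * (exp(gamma) - 1) * F_eps^{-1}(tau)`, exactly the
#' difference of the tau-quantiles between exposed and unexposed subjects.
#' Only available when exposures are independent (no copula correlation).
#'
#' @param config a [sim_config()] object.
#' @param factor name of the factor.
#' @param tau quantile level(s) in (0, 1).
#' @param age age group at which to evaluate (default: youngest).
#' @return true quantile effect(s) in diopters.
#' @export
true_quantile_effect <- function(config, factor, tau,
                                 age = min(config$age_groups)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$factor_corr > 0)
    stop_invalid("no closed form for correlated exposures")
  if (any(tau <= 0 | tau >= 1)) stop_invalid("tau must lie in (0, 1)")
  fnames <- vapply(config$factors, `[[`, character(1), "name")
  j <- match(factor, fnames)
  if (is.na(j)) stop_invalid("unknown factor: ", factor)
  f <- config$factors[[j]]
  m <- age_multiplier(config, factor, age)
  qe <- if (config$error_shape == "normal") qnorm(tau)
        else qskewnorm_std(tau, config$alpha)
  m * f$beta + config$sigma0 * (exp(m * f$gamma) - 1) * qe
}

#' Simulate a genotype dosage panel under Hardy-Weinberg equilibrium
#'
#' Emulates the dosage matrix backing a polygenic risk score: each variant
#' has a minor allele frequency drawn uniformly from `maf_range` and
#' per-subject dosages Binomial(2, maf).  Per-allele weights (diopters) are
#' drawn Normal(0, weight_sd) unless supplied.
#'
#' @param n_subjects,n_variants panel dimensions; both must be positive.
#' @param maf_range allele-frequency interval within (0, 0.5].
#' @param seed integer seed.
#' @param weights optional per-variant weights (diopters per allele).
#' @param weight_sd standard deviation of drawn weights.
#' @return an object of class `genotype_panel`: list with `variants`,
#'   `effect_allele`, `weights`, and `dosages` (variants x subjects matrix).
#' @export
simulate_genotypes <- function(n_subjects, n_variants,
                               maf_range = c(0.05, 0.5), seed,
                               weights = NULL, weight_sd = 0.05) {
  if (n_subjects < 1 || n_variants < 1)
    stop_invalid("n_subjects and n_variants must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_invalid("maf_range must lie within (0, 0.5]")
  if (missing(seed)) stop_invalid("a seed is mandatory")
  with_seed(seed, {
    maf <- runif(n_variants, maf_range[1], maf_range[2])
    dos <- matrix(rbinom(n_variants * n_subjects, 2, rep(maf, n_subjects)),
                  nrow = n_variants, ncol = n_subjects)
    if (is.null(weights)) weights <- rnorm(n_variants, 0, weight_sd)
    stopifnot(length(weights) == n_variants)
    ids <- sprintf("rs%05d", seq_len(n_variants))
    dimnames(dos) <- list(ids, sprintf("S%06d", seq_len(n_subjects)))
    structure(list(variants = ids,
                   effect_allele = rep("A", n_variants),
                   weights = setNames(weights, ids),
                   maf = setNames(maf, ids),
                   dosages = dos),
              class = "genotype_panel")
  })
}

#' Inject missing values into a cohort table
#'
#' Under MCAR each value of a column is deleted independently with the
#' column's rate.  Under MAR the deletion probability depends only on a
#' fully observed conditioning column: either per-level rates are given
#' explicitly (a named list whose elements are named vectors of rates per
#' level) or the marginal rate is split across the two levels of a binary
#' conditioning column in ratio `mar_ratio`.
#'
#' @param table a cohort `data.frame`.
#' @param rates named per-column missingness probabilities in `[0, 1)`, or
#'   for MAR optionally a named list of per-level named rate vectors.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param condition_on fully observed column driving MAR missingness.
#' @param mar_ratio rate ratio between level 1 and level 0 of a binary
#'   conditioning column when only marginal rates are given.
#' @param seed integer seed.
#' @return the table with `NA`s injected; observed values are unchanged.
#' @export
inject_missingness <- function(table, rates, mechanism = c("MCAR", "MAR"),
                               condition_on = NULL, mar_ratio = 2, seed) {
  mechanism <- match.arg(mechanism)
  if (missing(seed)) stop_invalid("a seed is mandatory")
  cols <- names(rates)
  if (!all(cols %in% names(table)))
    stop_invalid("rates name columns absent from the table: ",
                 paste(setdiff(cols, names(table)), collapse = ", "))
  flat <- unlist(rates)
  if (any(flat < 0) || any(flat >= 1))
    stop_invalid("missing rates must lie in [0, 1)")
  if (mechanism == "MAR") {
    if (is.null(condition_on) || !condition_on %in% names(table))
      stop_invalid("MAR requires an existing conditioning column")
    if (anyNA(table[[condition_on]]))
      stop_invalid("the MAR conditioning column must be fully observed")
  }
  n <- nrow(table)
  with_seed(seed, {
    for (col in cols) {
      r <- rates[[col]]
      if (mechanism == "MCAR") {
        p <- rep(r, n)
      } else if (length(r) > 1 || !is.null(names(r))) {
        lev <- as.character(table[[condition_on]])
        if (!all(lev %in% names(r)))
          stop_invalid("per-level rates missing for some levels of ",
                       condition_on)
        p <- unname(r[lev])
      } else {
        z <- table[[condition_on]]
        if (!is_binary01(z))
          stop_invalid("marginal-rate MAR needs a binary 0/1 conditioning column")
        pi1 <- mean(z == 1)
        r0 <- r / (1 - pi1 + mar_ratio * pi1)
        r1 <- min(mar_ratio * r0, 0.99)
        p <- ifelse(z == 1, r1, r0)
      }
      drop <- runif(n) < p
      table[[col]][drop] <- NA
    }
  })
  table
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  subjects:", x$n_subjects, " ages:",
      paste(x$age_groups, collapse = ", "), "\n")
  cat("  baseline: mu0 =", x$mu0, "D, sigma0 =", x$sigma0, "D, error:",
      x$error_shape,
      if (x$error_shape == "skew-normal") paste0("(alpha = ", x$alpha, ")"),
      "\n")
  for (f in x$factors)
    cat(sprintf("  factor %s: prevalence %.2f, beta %+.3f D, gamma %+.3f\n",
                f$name, f$prevalence, f$beta, f$gamma))
  invisible(x)
}
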