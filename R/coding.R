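# Phenotype and risk-factor coding -------------------------------------------

#' Spherical equivalent of a sphere/cylinder refraction
#'
#' The spherical equivalent is the sphere plus half the (negative-cylinder
#' convention) cylinder power. Missing inputs propagate to the output.
#'
#' @param sphere spherical power, diopters.
#' @param cyl cylindrical power, diopters.
#' @return spherical equivalent, diopters.
#' @examples
#' spherical_equivalent(-2, -1)   # -2.5
#' @export
spherical_equivalent <- function(sphere, cyl) sphere + cyl / 2

#' Mean spherical equivalent of the two eyes
#'
#' Averages the per-eye spherical equivalents; if only one eye was
#' measured, the available eye is used rather than dropping the subject.
#'
#' @param se_right,se_left per-eye spherical equivalents, diopters.
#' @return per-subject refractive error, diopters (`NA` when both missing).
#' @export
mean_refractive_error <- function(se_right, se_left) {
  both <- cbind(se_right, se_left)
  rowMeans(both, na.rm = TRUE) * ifelse(rowSums(!is.na(both)) == 0, NA, 1)
}

#' Polygenic risk score from a genotype panel
#'
#' The score is the weighted sum of risk-allele dosages,
#' `score_s = sum_v w_v d_vs`. Missing dosages may optionally be replaced
#' by the per-variant mean dosage (twice the sample allele frequency), the
#' standard practice for score construction.
#'
#' @param panel a `genotype_panel` (see [simulate_genotypes()]) or a list
#'   with `weights` (named per-variant) and `dosages` (variants x subjects).
#' @param impute_missing replace missing dosages by the per-variant mean
#'   dosage (default `TRUE`); with `FALSE`, missing dosages are an error.
#' @return named per-subject scores (diopters-weighted sums).
#' @export
compute_prs <- function(panel, impute_missing = TRUE) {
  w <- panel$weights
  d <- panel$dosages
  if (is.null(w) || is.null(d)) stop_invalid("panel needs weights and dosages")
  if (nrow(d) != length(w))
    stop_invalid("weights (", length(w), ") do not match variants (",
                 nrow(d), ")")
  if (!is.null(names(w)) && !is.null(rownames(d))) {
    if (!setequal(names(w), rownames(d)))
      stop_invalid("variant ids of weights and dosages differ")
    w <- w[rownames(d)]
  }
  if (anyNA(d)) {
    if (!impute_missing) stop_invalid("missing dosages present")
    rm_ <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- rm_[idx[, 1]]
  }
  s <- drop(crossprod(d, w))
  setNames(as.numeric(s), colnames(d))
}

#' Binarise polygenic risk scores into a high-risk indicator
#'
#' Scores are standardised to mean zero (centred; the split is invariant to
#' scale) and coded 1 where the centred score is strictly below zero —
#' below-average score meaning higher risk of a more negative refractive
#' error — and 0 otherwise. Missing scores stay missing.
#'
#' @param scores per-subject polygenic scores.
#' @return integer vector in \{0, 1, NA\}.
#' @examples
#' binarize_prs(c(1, 2, 3))  # 1 0 0
#' @export
binarize_prs <- function(scores) {
  obs <- !is.na(scores)
  if (sum(obs) < 2) stop_invalid("need at least 2 non-missing scores")
  centred <- scores - mean(scores[obs])
  as.integer(centred < 0)
}

#' Construct a questionnaire coding rule
#'
#' A coding rule maps declared response categories of one questionnaire
#' item to \{0, 1\} in the risk direction (1 = higher myopia risk).
#' Categories not declared map to missing with a warning.
#'
#' @param name rule name (e.g. `"time_reading"`).
#' @param cohort cohort the rule applies to.
#' @param mapping named vector/list: response category -> 0 or 1.
#' @return an object of class `coding_rule`.
#' @export
coding_rule <- function(name, cohort, mapping) {
  codes <- unlist(mapping)
  if (!all(codes %in% c(0, 1)))
    stop_invalid("mapping values must be 0 or 1")
  structure(list(name = name, cohort = cohort,
                 mapping = setNames(as.integer(codes), names(codes))),
            class = "coding_rule")
}

#' Apply a coding rule to a response column
#'
#' @param responses character/factor vector of questionnaire responses.
#' @param rule a [coding_rule()].
#' @return integer vector in \{0, 1, NA\}; undeclared categories become
#'   `NA` with a warning.
#' @export
apply_coding <- function(responses, rule) {
  stopifnot(inherits(rule, "coding_rule"))
  responses <- as.character(responses)
  out <- unname(rule$mapping[responses])
  unseen <- !is.na(responses) & is.na(out) &
    !(responses %in% names(rule$mapping))
  if (any(unseen))
    warning("undeclared response categories mapped to missing: ",
            paste(unique(responses[unseen]), collapse = ", "),
            call. = FALSE)
  as.integer(out)
}

#' Load a coding rule from a tab-separated mapping file
#'
#' The file has a header `response<TAB>code` and one row per declared
#' category. Rules for the two cohorts' reading and outdoors items ship
#' with the package under `inst/extdata/coding_rules`.
#'
#' @param path path to the mapping TSV.
#' @param name,cohort rule metadata; defaults parsed from the file name
#'   `<cohort>_<name>.tsv`.
#' @return a [coding_rule()].
#' @export
read_coding_rule <- function(path, name = NULL, cohort = NULL) {
  base <- sub("\\.tsv$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(cohort)) cohort <- parts[1]
  if (is.null(name)) name <- paste(parts[-1], collapse = "_")
  map <- read.delim(path, stringsAsFactors = FALSE)
  coding_rule(name, cohort, setNames(map$code, map$response))
}

#' Built-in questionnaire coding rules
#'
#' @return named list of the [coding_rule()]s shipped with the package
#'   (ALSPAC and Generation R reading/outdoors items).
#' @export
builtin_coding_rules <- function() {
  dir <- system.file("extdata", "coding_rules", package = "refractQR")
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  rules <- lapply(files, read_coding_rule)
  setNames(rules, vapply(rules, function(r) paste(r$cohort, r$name, sep = "_"),
                         character(1)))
}

# Response categories of the parental eyesight item
.myopic_responses <- c("cant_see_distance", "cant_see_much")
.nonmyopic_responses <- c("always_very_good", "cant_see_close_up")

#' Classify a parent as myopic from per-eye eyesight responses
#'
#' A parent is myopic when both eyes were reported as "can't see clearly at
#' a distance" or "can't see much at all" (or one of each), nonmyopic when
#' both eyes were "always very good" or "can't see clearly close up" (or
#' one of each); any other combination is missing.
#'
#' @param eye1,eye2 per-eye responses among `"always_very_good"`,
#'   `"cant_see_close_up"`, `"cant_see_distance"`, `"cant_see_much"`.
#' @return character vector in `"myopic"`, `"nonmyopic"`, `NA`.
#' @export
classify_parent_myopia_alspac <- function(eye1, eye2) {
  eye1 <- as.character(eye1); eye2 <- as.character(eye2)
  out <- rep(NA_character_, length(eye1))
  myo <- eye1 %in% .myopic_responses & eye2 %in% .myopic_responses
  non <- eye1 %in% .nonmyopic_responses & eye2 %in% .nonmyopic_responses
  out[myo] <- "myopic"
  out[non] <- "nonmyopic"
  out
}

#' Combine the two parents' myopia classifications into one binary factor
#'
#' Coded 1 when at least one parent is myopic; 0 when both are classified
#' nonmyopic; missing when no parent is myopic but at least one
#' classification is missing (the observed parent being nonmyopic cannot
#' rule out myopia in the unobserved one).
#'
#' @param mother,father classifications in `"myopic"`, `"nonmyopic"`, `NA`.
#' @return integer vector in \{0, 1, NA\}.
#' @export
combine_parental_myopia <- function(mother, father) {
  m <- as.character(mother); f <- as.character(father)
  out <- rep(NA_integer_, length(m))
  any_myopic <- (!is.na(m) & m == "myopic") | (!is.na(f) & f == "myopic")
  both_non <- !is.na(m) & !is.na(f) & m == "nonmyopic" & f == "nonmyopic"
  out[any_myopic] <- 1L
  out[both_non] <- 0L
  out
}
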