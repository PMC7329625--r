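# Interchange formats ---------------------------------------------------------
# Cohort tables travel as UTF-8 TSV with a header row; missing values are
# empty fields.  Genotype panels are a weights TSV (variant_id,
# effect_allele, weight) and a dosage TSV (variants x subjects with a
# header row of subject ids).  Configurations are YAML.

#' Read and write cohort tables as TSV
#'
#' @param table a cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns a data frame; `write_cohort` invisibly
#'   returns `path`.
#' @export
write_cohort <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, na = "",
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.delim(path, na.strings = "", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

#' Read and write genotype panels
#'
#' @param panel a `genotype_panel`.
#' @param weights_path path of the weights TSV (`variant_id`,
#'   `effect_allele`, `weight`).
#' @param dosages_path path of the dosage TSV (variants x subjects).
#' @return `read_genotype_panel` returns a `genotype_panel`;
#'   `write_genotype_panel` invisibly returns the paths.
#' @export
write_genotype_panel <- function(panel, weights_path, dosages_path) {
  w <- data.frame(variant_id = panel$variants,
                  effect_allele = panel$effect_allele,
                  weight = unname(panel$weights))
  write.table(w, weights_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  d <- data.frame(variant_id = rownames(panel$dosages),
                  panel$dosages, check.names = FALSE)
  write.table(d, dosages_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(weights_path, dosages_path))
}

#' @rdname write_genotype_panel
#' @export
read_genotype_panel <- function(weights_path, dosages_path) {
  w <- read.delim(weights_path, stringsAsFactors = FALSE)
  d <- read.delim(dosages_path, check.names = FALSE,
                  stringsAsFactors = FALSE)
  dos <- as.matrix(d[, -1, drop = FALSE])
  rownames(dos) <- d[[1]]
  if (!setequal(w$variant_id, rownames(dos)))
    stop_invalid("weights and dosages name different variants")
  dos <- dos[w$variant_id, , drop = FALSE]
  structure(list(variants = w$variant_id,
                 effect_allele = w$effect_allele,
                 weights = setNames(w$weight, w$variant_id),
                 dosages = dos),
            class = "genotype_panel")
}

# Serialise a sim_config to/from plain named lists for YAML round trips.
sim_config_to_list <- function(config) {
  lst <- unclass(config)
  lst$factors <- lapply(config$factors, unclass)
  lst$age_slope <- as.list(config$age_slope)
  lst$missing_rates <- if (is.null(config$missing_rates)) NULL
                       else as.list(config$missing_rates)
  lst
}

sim_config_from_list <- function(lst) {
  sim_config(n_subjects = lst$n_subjects,
             age_groups = unlist(lst$age_groups),
             factors = lapply(lst$factors, function(f)
               factor_spec(f$name, f$prevalence, f$beta %||% 0,
                           f$gamma %||% 0)),
             mu0 = lst$mu0 %||% 0.1, sigma0 = lst$sigma0 %||% 1.3,
             error_shape = lst$error_shape %||% "skew-normal",
             alpha = lst$alpha %||% -4,
             age_slope = unlist(lst$age_slope),
             factor_corr = lst$factor_corr %||% 0,
             missing_rates = unlist(lst$missing_rates),
             mechanism = lst$mechanism %||% "MCAR",
             mar_condition = lst$mar_condition %||% "sex",
             mar_ratio = lst$mar_ratio %||% 2,
             seed = lst$seed)
}

#' Read and write simulation configurations as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   invisibly returns `path`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(sim_config_to_list(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  sim_config_from_list(yaml::read_yaml(path))
}
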