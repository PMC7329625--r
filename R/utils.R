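#' @keywords internal
"_PACKAGE"

#' @useDynLib refractQR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats as.formula coef complete.cases dnorm glm integrate lm
#'   median model.matrix model.response model.frame optim pchisq plogis pnorm
#'   predict pt qchisq qnorm quantile rbinom reformulate rnorm runif sd
#'   setNames terms update uniroot var vcov loess rchisq binomial delete.response
#' @importFrom utils read.delim write.table combn head
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic child seed: offsets a base seed by a stage label so that
# independent pipeline stages use independent, reproducible streams while
# staying inside the 32-bit integer range.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * (seq_along(utf8ToInt(as.character(stage))) %% 97 + 1))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

is_binary01 <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) > 0 && all(u %in% c(0, 1))
}
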