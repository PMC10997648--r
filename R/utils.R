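#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom plogis qlogis sd var cov weighted.mean
#'   lm lm.wfit glm binomial coef resid pt qt quantile setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed deterministically yields distinct, reproducible
#' sub-seeds for each named stage, so stages can be re-run in isolation.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  p <- 2147483647  # 2^31 - 1; all arithmetic stays exact in doubles
  h <- abs(seed) %% p
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% p
  as.integer((h * 48271) %% (p - 1)) + 1L
}

stop_defoeval <- function(msg, class) {
  stop(structure(class = c(class, "defoeval_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
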