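#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm rexp runif rbinom sd var cor pt qnorm
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a per-stage random seed from the global run seed
#'
#' One global seed fans out deterministically to named pipeline stages, so a
#' stage can be rerun in isolation and reproduce exactly the draws it saw
#' inside a full run.
#'
#' @param seed Non-negative integer global seed.
#' @param stage Character stage label (e.g. `"atlas"`, `"masks"`).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 99991
  as.integer(((seed %% 20000) * 100003 + h * 7 + 1) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s].", name, min, max))
  }
  invisible(x)
}

frobenius <- function(x) sqrt(sum(x^2))
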