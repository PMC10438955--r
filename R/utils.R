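# Structured conditions: every user-facing failure carries a class so callers
# (and the batch runner) can react programmatically.
cgStop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "cytogateError")))
}

cgWarn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "cytogateWarning")))
}

# Deterministic 32-bit string hash (polynomial rolling hash mod a Mersenne
# prime); used to derive per-sample seeds independent of execution order.
stringHash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Derive a per-sample random seed
#'
#' Combines the experiment's global seed with a sample id so that stochastic
#' gates are reproducible per sample, independent of worker scheduling and
#' execution order.
#'
#' @param seed Global integer seed.
#' @param id Sample id.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
deriveSeed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + stringHash(id)) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# integer coercion that refuses NAs silently introduced by as.integer
asCount <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) cgStop("cg_validation_error", "%s must be integer-valued", what)
  v
}
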