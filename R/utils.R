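# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so simulation functions are reproducible without clobbering the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 100 * num / den, defined as 0 when the denominator is 0.
pct_of <- function(num, den) {
  if (length(den) == 1L && den == 0) return(0)
  ifelse(den == 0, 0, 100 * num / den)
}

# Vectorised draw of one integer uniformly from 1..m per element (m >= 1),
# using runif so draws interleave deterministically with other RNG use.
runif_int <- function(m) {
  r <- floor(runif(length(m)) * m) + 1L
  as.integer(pmin(r, m))
}

stop_carefrag <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "carefrag_error")))
}
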