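# Internal helpers: seeded evaluation, hierarchical seed derivation, the
# clipped-logistic squash used by the simulator.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package internals do
#' not perturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and a path of tags
#'
#' Deterministic polynomial hash over the tag path, reduced modulo a prime
#' below 2^31. Gives every (participant, stage, fold, ...) its own stream so
#' subsets of a simulation are reproducible independently of the whole.
#' @noRd
derive_seed <- function(seed, ...) {
  tags <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 7
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483587
  as.integer(h + 1L)
}

#' Logistic squash with optional clipping floor
#'
#' `floor` bounds the output away from 0 and 1 (default 0.02) so simulated
#' cells are never deterministically all-zero or all-five unless explicitly
#' requested with `floor = 0`.
#' @noRd
squash <- function(x, floor = 0.02) {
  stopifnot(floor >= 0, floor < 0.5)
  p <- stats::plogis(x)
  pmin(pmax(p, floor), 1 - floor)
}

#' Assert that a value is a single finite number
#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
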