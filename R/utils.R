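# Internal helpers shared across the package.

#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a stage seed from a base seed
#'
#' All randomness in the package flows from a single user-supplied integer
#' seed. Stages (record generation, trajectory realization, bootstrap
#' resampling, ...) use seeds derived deterministically from the base seed
#' with this splitting scheme, so that changing one stage's stream never
#' perturbs another's.
#'
#' @param seed integer base seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647           # 2^31 - 1, keeps derived seeds in integer range
  as.integer((abs(seed) %% m * 48271 + 1009 * (stream + 1)) %% m)
}

#' @noRd
stop_domain <- function(...) stop(..., call. = FALSE)

# Behavior labels, in ascending order of avoidance strength.
#' @noRd
behavior_levels <- function() c("CONT", "PAUSE", "TURN", "REV")

#' @noRd
as_behavior <- function(x) factor(x, levels = behavior_levels())

# Binomial SEM of a fraction k/n with a half-count smoothing so that
# zero-count bins keep a nonzero uncertainty.
#' @noRd
binomial_sem <- function(k, n) {
  p <- (k + 0.5) / (n + 1)
  sqrt(p * (1 - p) / n)
}
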