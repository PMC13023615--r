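# Small shared helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded internals (searches, validation splits) do not perturb the
#' surrounding random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Spectral angle (radians) between aligned rows of two matrices, with the
# cosine clamped to [-1, 1] to absorb floating-point overshoot.
spectral_angle_rows <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  if (any(den == 0)) stop("spectral angle undefined for zero-norm spectrum")
  acos(pmin(1, pmax(-1, num / den)))
}

# deterministic integer sub-seed derived from a master seed, kept < 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
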