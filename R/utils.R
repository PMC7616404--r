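#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit hash of a character label, for seed derivation.
label_hash <- function(label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' Every stochastic operation in the package draws its seed as a pure
#' function of the run's global seed and a stable string label, so that a
#' single `--seed` reproduces a whole pipeline while its stages remain
#' decoupled.
#'
#' @param seed integer global seed.
#' @param label character label naming the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- label_hash(label)
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

# Run expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Peak signal-to-noise ratio in dB for intensities on a [0, 1] scale.
#' Peak signal-to-noise ratio
#' @param x,y numeric arrays of identical shape on a `[0, 1]` intensity scale.
#' @param peak signal peak (default 1).
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y, peak = 1) {
  mse <- mean((as.numeric(x) - as.numeric(y))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
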