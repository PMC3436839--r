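#' Derive a named sub-seed from a root seed
#'
#' All randomized operations in the package draw their seeds from a single
#' root seed through named substreams, so that e.g. fingerprint generation
#' and fold assignment are decoupled: changing the number of folds never
#' perturbs the fingerprints. The derivation hashes the stream name parts
#' into a 31-bit integer combined with the root seed.
#'
#' @param seed integer root seed.
#' @param ... stream name parts (characters or numbers), e.g.
#'   `derive_seed(7, "negatives", "repeat", 2)`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483563
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m + h) %% (m - 1)) + 1L
}
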