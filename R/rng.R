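# Deterministic named sub-streams: every stochastic stage draws from a seed
# derived from (top-level seed, stage name), so adding or reordering stages
# never perturbs the draws of the others.

#' Derive a stage-specific seed from a top-level seed
#'
#' All randomness in the package flows from one top-level seed through named
#' sub-streams, one per simulation stage. The derived seed is a deterministic
#' hash of the seed and the stage name, kept below 2^31.
#'
#' @param seed Integer top-level seed.
#' @param name Character stage name (e.g. `"genome"`, `"selection"`).
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1, "genome")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(name), length(name) == 1L)
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483629
  as.integer(((abs(seed) %% 1048576) * 2039 + h) %% 2147483629)
}

# Evaluate `code` under the sub-stream seed, restoring the caller's RNG state.
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}
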