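#' Derive a deterministic substream seed
#'
#' Expands one global integer seed into independent per-stream seeds by a
#' fixed integer mix, so that e.g. genotype draws, methylation noise and
#' missingness masks come from reproducible, stage-independent streams.
#' All arithmetic stays below 2^31 so the result is a valid R seed.
#'
#' @param seed Global integer seed.
#' @param ... One or more non-negative integer offsets identifying the
#'   stream (stage index, locus index, replicate index, ...).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (off in c(...)) {
    s <- (s * 69069 + as.numeric(off) * 30011 + 1013904223) %% m
  }
  as.integer(s)
}
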