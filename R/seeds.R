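# Seed plumbing: one user-facing seed fans out to named substreams so the
# confidence interval, the two permutation statistics, and the synthetic
# generators draw from independent, individually reproducible streams.

#' Derive a named substream seed
#'
#' Deterministically maps (seed, name) to an integer in [1, 2^31 - 2] so
#' every source of randomness in a run is reproducible from the single
#' top-level seed yet independent across uses.
#'
#' @param seed integer master seed.
#' @param name substream label, e.g. \code{"ci"}, \code{"o"}, \code{"k"}.
#' @return integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  # multipliers small enough that the arithmetic stays exact in doubles
  s <- (abs(as.numeric(seed)) %% 2147483647) * 69069 + h * 2654435
  as.integer(s %% 2147483646) + 1L
}

# evaluate expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
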