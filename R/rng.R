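#' Derive a reproducible substream seed
#'
#' Mixes a master seed with an iteration index and a stream tag into a single
#' integer seed, so that every iteration of a study (and every randomised
#' stage within an iteration) gets its own deterministic stream. Because the
#' seed depends only on `(master_seed, iteration, stream)` and not on how many
#' iterations ran before it, any partition of iterations across processes
#' reproduces the monolithic run exactly.
#'
#' The mixer is a multiplicative congruential hash modulo the Mersenne prime
#' 2^31 - 1, computed in double precision (all intermediates stay below 2^53,
#' so the arithmetic is exact).
#'
#' @param master_seed integer master seed for the whole study.
#' @param iteration iteration index (1-based), or a grid index for sweeps.
#' @param stream small integer tag separating the randomised stages within one
#'   iteration (data generation, without-U draws, with-U draws, ...).
#' @return a single integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' substream_seed(42, 1) != substream_seed(42, 2)
#' @export
substream_seed <- function(master_seed, iteration, stream = 0L) {
  m <- 2147483647 # 2^31 - 1
  h <- abs(as.numeric(master_seed)) %% m
  for (k in c(as.numeric(iteration), as.numeric(stream))) {
    h <- (h * 69069) %% m
    h <- (h + abs(k)) %% m
  }
  h <- (h * 69069) %% m
  # avoid the degenerate 0 seed; result is always < 2^31
  as.integer(h %% (m - 1L)) + 1L
}
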