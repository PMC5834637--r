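# Seed plumbing: every generator takes an explicit seed and leaves the
# caller's RNG state untouched; pipeline stages derive independent
# substreams from one master seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a stage-specific RNG substream from a master seed
#'
#' Stages of a pipeline run must be independently re-runnable, so a single
#' master seed is fanned out deterministically: the stream label is folded
#' into the seed with a small string hash. Results stay below 2^31 so they
#' are valid R integer seeds.
#'
#' @param seed master seed (integer).
#' @param label character stage label, e.g. `"island3/detect"`.
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1, "detect") != substream_seed(1, "filter")
substream_seed <- function(seed, label) {
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% p
  }
  s <- (as.numeric(seed) %% p * 2654435 + h) %% p
  # Lehmer steps diffuse adjacent labels ("arch1", "arch2", ...) far apart,
  # so the derived Mersenne-Twister streams are decorrelated
  for (i in 1:3) s <- (s * 48271) %% p
  as.integer(s)
}

# truncated-at-zero normal draws on the count scale
rnorm_trunc0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0]
    guard <- guard + 1L
  }
  pmax(x, 0)
}
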