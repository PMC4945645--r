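#' IAAFT surrogate of a single time series
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: a randomised
#' series that preserves the amplitude distribution of the input exactly
#' (its sorted values equal the sorted input values) and its Fourier
#' amplitude spectrum approximately, destroying any higher-order temporal
#' structure. The iteration alternates (i) imposing the original amplitude
#' spectrum on the current surrogate's phases and (ii) rank-remapping onto
#' the sorted original values; it stops when the rank ordering stabilises or
#' after `maxIter` iterations.
#'
#' @param x numeric vector, length >= 8, not constant.
#' @param maxIter maximum number of refinement iterations.
#' @param seed integer seed for the initial random permutation.
#' @return numeric surrogate series of the same length; attribute
#'   `"iterations"` records the iterations used.
#' @references Schreiber & Schmitz, Phys. Rev. Lett. 77, 635 (1996).
#' @export
iaaftSurrogate <- function(x, maxIter = 100L, seed = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("series must have length >= 8")
  if (max(x) == min(x)) {
    stop("constant series: spectrum/rank iteration is undefined")
  }
  assertCount(maxIter, "maxIter")
  amp <- Mod(stats::fft(x))
  xs <- sort(x)
  run <- function() {
    s <- x[sample.int(n)]
    iters <- 0L
    prevRank <- integer(0)
    for (it in seq_len(maxIter)) {
      iters <- it
      f <- stats::fft(s)
      # impose the target amplitude spectrum, keep current phases
      s2 <- Re(stats::fft(amp * exp(1i * Arg(f)), inverse = TRUE)) / n
      r <- rank(s2, ties.method = "first")
      if (identical(r, prevRank)) break
      prevRank <- r
      s <- xs[r]
    }
    structure(xs[rank(s, ties.method = "first")], iterations = iters)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}
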