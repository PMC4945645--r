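# Welch-averaged magnitude-squared coherence and the surrogate-thresholded
# band networks built from it.

# Hann-tapered, mean-detrended segment FFTs of all channels.
# Returns list(X = nfreq x nseg x nchan complex array, freqs = Hz).
segmentFFTs <- function(values, trSeconds, segLen = NULL) {
  n <- ncol(values)
  if (is.null(segLen)) segLen <- min(n, 64L)
  segLen <- as.integer(segLen)
  step <- max(1L, segLen %/% 2L) # 50% overlap
  starts <- seq.int(1L, n - segLen + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq.int(0L, segLen - 1L) / segLen))
  nf <- segLen %/% 2L + 1L
  X <- array(0i, dim = c(nf, length(starts), nrow(values)))
  for (ch in seq_len(nrow(values))) {
    for (s in seq_along(starts)) {
      seg <- values[ch, starts[s]:(starts[s] + segLen - 1L)]
      seg <- (seg - mean(seg)) * win
      X[, s, ch] <- stats::fft(seg)[seq_len(nf)]
    }
  }
  fs <- 1 / trSeconds
  list(X = X, freqs = (seq_len(nf) - 1L) * fs / segLen, nSegments = length(starts))
}

# Indices of the spectral bins belonging to each band (half-open [low, high);
# a bin at the scheme's upper edge is assigned to the top band so no bin
# inside the analysed range is orphaned).
bandBinIndices <- function(freqs, scheme) {
  e <- scheme@edges
  nb <- nrow(e)
  bins <- vector("list", nb)
  for (b in seq_len(nb)) {
    inBand <- freqs >= e[b, 1] - 1e-12 & freqs < e[b, 2] - 1e-12
    if (b == nb) inBand <- inBand | abs(freqs - e[b, 2]) <= 1e-12
    bins[[b]] <- which(inBand)
  }
  bins
}

# Band-averaged MSC for all channel pairs from precomputed segment FFTs.
# Returns an N x N x B array.
bandCoherenceFromFFT <- function(X, bins) {
  nf <- dim(X)[1]
  nch <- dim(X)[3]
  nb <- length(bins)
  # mean auto-spectra per channel
  Pxx <- matrix(0, nf, nch)
  for (ch in seq_len(nch)) Pxx[, ch] <- rowMeans(Mod(X[, , ch, drop = FALSE])^2)
  w <- array(0, dim = c(nch, nch, nb))
  for (i in seq_len(nch - 1L)) {
    Xi <- Conj(X[, , i])
    for (j in seq.int(i + 1L, nch)) {
      Sxy <- rowMeans(X[, , j] * Xi)
      coh <- Mod(Sxy)^2 / (Pxx[, i] * Pxx[, j])
      for (b in seq_len(nb)) {
        w[i, j, b] <- w[j, i, b] <- mean(coh[bins[[b]]])
      }
    }
  }
  pmin(w, 1)
}

#' Band-averaged magnitude-squared coherence between all channel pairs
#'
#' Estimates the magnitude-squared coherence spectrum for every channel pair
#' with Welch's method (segments of `min(T, 64)` samples, 50% overlap, Hann
#' taper, per-segment mean removal) and averages it over the spectral bins
#' falling inside each band of `scheme`.
#'
#' @param ts a \linkS4class{RoiTimeSeriesSet}.
#' @param scheme a \linkS4class{FrequencyBandScheme}; all bands must lie at
#'   or below the Nyquist frequency `1/(2 trSeconds)`.
#' @param segLen Welch segment length in samples (default `min(T, 64)`).
#' @return a \linkS4class{BandConnectivity}.
#' @export
bandCoherence <- function(ts, scheme, segLen = NULL) {
  stopifnot(is(ts, "RoiTimeSeriesSet"), is(scheme, "FrequencyBandScheme"))
  nyq <- 1 / (2 * ts@trSeconds)
  if (max(scheme@edges) > nyq + 1e-9) {
    stop(sprintf(
      "band scheme reaches %g Hz but the Nyquist frequency is only %g Hz",
      max(scheme@edges), nyq
    ))
  }
  sf <- segmentFFTs(ts@values, ts@trSeconds, segLen)
  bins <- bandBinIndices(sf$freqs, scheme)
  empty <- which(lengths(bins) == 0L)
  if (length(empty)) {
    stop(sprintf(
      paste0(
        "band %d ([%g, %g) Hz) contains no spectral bins; ",
        "lengthen the series or widen the bands"
      ),
      empty[1], scheme@edges[empty[1], 1], scheme@edges[empty[1], 2]
    ))
  }
  w <- bandCoherenceFromFFT(sf$X, bins)
  dimnames(w) <- list(ts@roiIds, ts@roiIds, NULL)
  new("BandConnectivity", w = w, scheme = scheme)
}

#' Build significance-thresholded band networks from one subject's series
#'
#' For each frequency band, estimates the band-averaged coherence of every
#' channel pair, builds an IAAFT surrogate null (both channels of a pair are
#' replaced by independent surrogates; surrogate replicates are paired
#' one-to-one), computes the absolute z-score
#' `z_ij = |w_ij - mu_ij| / sigma_ij`, discards edges with `z_ij` below the
#' threshold and uses the retained z-scores as edge weights of the band's
#' \linkS4class{LayerNetwork}. The absolute value means significantly
#' correlated and anti-correlated signals are not distinguished.
#'
#' @param ts a \linkS4class{RoiTimeSeriesSet}.
#' @param scheme a \linkS4class{FrequencyBandScheme}.
#' @param nSurrogates number of surrogate replicates (>= 20; default 100).
#' @param zThreshold retention threshold on the absolute z-score (default 3).
#' @param seed integer seed controlling the surrogate draws.
#' @param segLen Welch segment length passed to [bandCoherence()].
#' @return a list with elements `layers` (list of
#'   \linkS4class{LayerNetwork}, one per band), `null`
#'   (\linkS4class{SurrogateNull}), `coherence`
#'   (\linkS4class{BandConnectivity}) and `z` (the full N x N x B z-score
#'   array before thresholding).
#' @export
buildLayers <- function(ts, scheme, nSurrogates = 100L, zThreshold = 3,
                        seed = 1L, segLen = NULL) {
  stopifnot(is(ts, "RoiTimeSeriesSet"), is(scheme, "FrequencyBandScheme"))
  assertCount(nSurrogates, "nSurrogates", min = 20L)
  if (zThreshold <= 0) stop("zThreshold must be positive")
  wObs <- bandCoherence(ts, scheme, segLen)
  n <- nNodes(ts)
  nb <- nBands(scheme)
  vals <- ts@values
  tLen <- ncol(vals)
  segL <- if (is.null(segLen)) min(tLen, 64L) else as.integer(segLen)
  bins <- bandBinIndices(segmentFFTs(vals[1:2, , drop = FALSE],
    ts@trSeconds, segL
  )$freqs, scheme)

  s1 <- array(0, dim = c(n, n, nb))
  s2 <- s1
  s3 <- s1
  s4 <- s1
  surro <- matrix(0, n, tLen)
  for (r in seq_len(nSurrogates)) {
    for (ch in seq_len(n)) {
      surro[ch, ] <- iaaftSurrogate(vals[ch, ],
        seed = deriveSeed(seed, (ch - 1L) * nSurrogates + r)
      )
    }
    sf <- segmentFFTs(surro, ts@trSeconds, segL)
    wS <- bandCoherenceFromFFT(sf$X, bins)
    s1 <- s1 + wS
    s2 <- s2 + wS^2
    s3 <- s3 + wS^3
    s4 <- s4 + wS^4
  }
  m <- nSurrogates
  mu <- s1 / m
  varP <- pmax(s2 / m - mu^2, 0) # population variance
  sigma <- sqrt(varP * m / (m - 1))
  m3 <- s3 / m - 3 * mu * s2 / m + 2 * mu^3
  m4 <- s4 / m - 4 * mu * s3 / m + 6 * mu^2 * s2 / m - 3 * mu^4
  skew <- ifelse(varP > 0, m3 / varP^1.5, NA_real_)
  kurt <- ifelse(varP > 0, m4 / varP^2 - 3, NA_real_)

  offDiag <- !diag(n)
  zeroSig <- which(sigma == 0 & array(offDiag, dim = dim(sigma)), arr.ind = TRUE)
  if (nrow(zeroSig)) {
    stop(sprintf(
      "degenerate surrogate null (sigma = 0) for pair (%d, %d) in band %d",
      zeroSig[1, 1], zeroSig[1, 2], zeroSig[1, 3]
    ))
  }
  z <- abs(wObs@w - mu) / sigma
  for (b in seq_len(nb)) diag(z[, , b]) <- 0

  layers <- vector("list", nb)
  for (b in seq_len(nb)) {
    zb <- z[, , b]
    zb[zb < zThreshold] <- 0
    diag(zb) <- 0
    layers[[b]] <- new("LayerNetwork",
      z = zb, band = as.numeric(scheme@edges[b, ]),
      threshold = zThreshold
    )
  }
  nullObj <- new("SurrogateNull",
    mu = mu, sigma = sigma, skewness = skew, kurtosis = kurt,
    nSurrogates = as.integer(nSurrogates)
  )
  list(layers = layers, null = nullObj, coherence = wObs, z = z)
}

#' Conventional single-band baseline network
#'
#' Builds the "full-band" (e.g. 0.01-0.25 Hz) or "typical-band"
#' (0.01-0.1 Hz) single-layer baseline: coherence is averaged over the whole
#' range treated as one band and then surrogate-thresholded exactly as in
#' [buildLayers()].
#'
#' @inheritParams buildLayers
#' @param fLow,fHigh range edges in Hz.
#' @return a \linkS4class{LayerNetwork}.
#' @export
conventionalBandNetwork <- function(ts, fLow, fHigh, nSurrogates = 100L,
                                    zThreshold = 3, seed = 1L, segLen = NULL) {
  scheme <- makeBandScheme(fLow, fHigh, fHigh - fLow)
  buildLayers(ts, scheme, nSurrogates, zThreshold, seed, segLen)$layers[[1]]
}
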