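#' Build a contiguous equal-width frequency band scheme
#'
#' Decomposes the range `[fLow, fHigh)` into contiguous half-open bands of
#' equal width. The default analysis decomposes 0.01-0.25 Hz into 12 bands
#' of 0.02 Hz each.
#'
#' @param fLow lower edge of the range in Hz.
#' @param fHigh upper edge of the range in Hz.
#' @param width band width in Hz; `fHigh - fLow` must be an integer multiple
#'   of `width` (no silent truncation).
#' @return a \linkS4class{FrequencyBandScheme}.
#' @examples
#' makeBandScheme(0.01, 0.25, 0.02) # 12 bands
#' @export
makeBandScheme <- function(fLow, fHigh, width) {
  if (fLow >= fHigh) stop("fLow must be smaller than fHigh")
  if (width <= 0) stop("width must be positive")
  nb <- (fHigh - fLow) / width
  if (abs(nb - round(nb)) > 1e-9) {
    stop(sprintf(
      "band width %g does not divide the range [%g, %g) evenly",
      width, fLow, fHigh
    ))
  }
  nb <- as.integer(round(nb))
  lows <- fLow + width * (seq_len(nb) - 1L)
  new("FrequencyBandScheme", edges = cbind(lows, lows + width, deparse.level = 0))
}

#' Construct an ROI time-series set
#'
#' @param values channels x time numeric matrix.
#' @param trSeconds sampling interval in seconds.
#' @param roiIds optional channel labels (default "roi1", "roi2", ...).
#' @return a \linkS4class{RoiTimeSeriesSet}.
#' @export
roiTimeSeriesSet <- function(values, trSeconds, roiIds = NULL) {
  values <- as.matrix(values)
  if (is.null(roiIds)) roiIds <- paste0("roi", seq_len(nrow(values)))
  new("RoiTimeSeriesSet",
    values = values, trSeconds = trSeconds,
    roiIds = as.character(roiIds)
  )
}
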