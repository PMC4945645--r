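# ---- accessors ----------------------------------------------------------
#' @describeIn nNodes node count of a time-series set (channels)
#' @export
setMethod("nNodes", "RoiTimeSeriesSet", function(x) nrow(x@values))

#' @describeIn nNodes node count of a layer
#' @export
setMethod("nNodes", "LayerNetwork", function(x) nrow(x@z))

#' @describeIn nNodes shared node count of a multiplex
#' @export
setMethod("nNodes", "MultiplexNetwork", function(x) nrow(x@layers[[1]]@z))

#' @describeIn nNodes node count of a centrality profile
#' @export
setMethod("nNodes", "CentralityProfile", function(x) nrow(x@piStar))

#' @describeIn nLayers layer count of a multiplex
#' @export
setMethod("nLayers", "MultiplexNetwork", function(x) length(x@layers))

#' @describeIn nLayers layer count of a centrality profile
#' @export
setMethod("nLayers", "CentralityProfile", function(x) ncol(x@piStar))

#' @describeIn nBands band count of a scheme
#' @export
setMethod("nBands", "FrequencyBandScheme", function(x) nrow(x@edges))

#' @describeIn nBands band count of a connectivity array
#' @export
setMethod("nBands", "BandConnectivity", function(x) dim(x@w)[3])

#' @describeIn bandEdges band edge matrix
#' @export
setMethod("bandEdges", "FrequencyBandScheme", function(x) {
  e <- x@edges
  colnames(e) <- c("low", "high")
  e
})

#' @describeIn adjacency z-score adjacency of a layer
#' @export
setMethod("adjacency", "LayerNetwork", function(x) x@z)

#' @describeIn nodeProfile per-node multiplex PageRank
#' @export
setMethod("nodeProfile", "CentralityProfile", function(x) rowSums(x@piStar))

# ---- show methods -------------------------------------------------------

setMethod("show", "FrequencyBandScheme", function(object) {
  e <- object@edges
  cat(sprintf(
    "FrequencyBandScheme: %d bands of width %.4g Hz covering [%.4g, %.4g) Hz\n",
    nrow(e), e[1, 2] - e[1, 1], e[1, 1], e[nrow(e), 2]
  ))
})

setMethod("show", "RoiTimeSeriesSet", function(object) {
  cat(sprintf(
    "RoiTimeSeriesSet: %d ROIs x %d time points, TR = %g s (Nyquist %.4g Hz)\n",
    nrow(object@values), ncol(object@values), object@trSeconds,
    1 / (2 * object@trSeconds)
  ))
})

setMethod("show", "LayerNetwork", function(object) {
  m <- sum(object@z[upper.tri(object@z)] != 0)
  bd <- if (anyNA(object@band)) "unbanded" else {
    sprintf("[%.4g, %.4g) Hz", object@band[1], object@band[2])
  }
  cat(sprintf(
    "LayerNetwork: %d nodes, %d edges, band %s, z threshold %g\n",
    nrow(object@z), m, bd, object@threshold
  ))
})

setMethod("show", "MultiplexNetwork", function(object) {
  cat(sprintf(
    "MultiplexNetwork: %d nodes x %d layers, inter-layer weight D = %g\n",
    nNodes(object), nLayers(object), object@D
  ))
})

setMethod("show", "CentralityProfile", function(object) {
  cat(sprintf(
    "CentralityProfile: %d nodes x %d layers (D = %g), %d iterations, residual %.2e\n",
    nNodes(object), nLayers(object), object@D, object@iterations,
    object@residual
  ))
})

setMethod("show", "ReducibilityResult", function(object) {
  cat(sprintf(
    "ReducibilityResult: %d layers, optimal reduction step %d (q = %.4g)\n",
    nrow(object@distanceMatrix), object@optimalStep,
    object@quality[object@optimalStep + 1L]
  ))
})
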