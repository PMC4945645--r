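#' Number of nodes in a network object
#'
#' @param x a \linkS4class{LayerNetwork}, \linkS4class{MultiplexNetwork},
#'   \linkS4class{RoiTimeSeriesSet} or \linkS4class{CentralityProfile}.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of layers of a multiplex object
#'
#' @param x a \linkS4class{MultiplexNetwork} or
#'   \linkS4class{CentralityProfile}.
#' @return integer layer count.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Number of frequency bands in a band scheme
#'
#' @param x a \linkS4class{FrequencyBandScheme} or
#'   \linkS4class{BandConnectivity}.
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Band edges of a scheme
#'
#' @param x a \linkS4class{FrequencyBandScheme}.
#' @return a two-column matrix of (low, high) band edges in Hz.
#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))

#' Weighted adjacency matrix of a network object
#'
#' For a \linkS4class{LayerNetwork} this is the symmetric matrix of retained
#' surrogate z-scores (zero where an edge was discarded).
#'
#' @param x a network object.
#' @return a numeric matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Per-node centrality profile
#'
#' The per-node multiplex PageRank, i.e. the stationary probability of each
#' node summed over its layer replicas.
#'
#' @param x a \linkS4class{CentralityProfile}.
#' @return numeric vector summing to 1.
#' @export
setGeneric("nodeProfile", function(x) standardGeneric("nodeProfile"))
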