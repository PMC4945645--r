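#' Contiguous equal-width frequency band scheme
#'
#' Ordered, contiguous, non-overlapping half-open intervals `[low, high)`
#' of equal width, covering one frequency range. Each band becomes one layer
#' of the multiplex functional network.
#'
#' @slot edges two-column numeric matrix; row b holds (low, high) of band b
#'   in Hz.
#' @seealso [makeBandScheme()]
#' @export
setClass("FrequencyBandScheme", representation(edges = "matrix"))

setValidity("FrequencyBandScheme", function(object) {
  e <- object@edges
  if (!is.matrix(e) || ncol(e) != 2L || nrow(e) < 1L) {
    return("edges must be a B x 2 matrix")
  }
  if (any(e[, 2] <= e[, 1])) return("each band must have low < high")
  if (nrow(e) > 1L) {
    if (max(abs(e[-1L, 1] - e[-nrow(e), 2])) > 1e-9) {
      return("bands must be contiguous")
    }
    widths <- e[, 2] - e[, 1]
    if (max(widths) - min(widths) > 1e-9) return("bands must have equal widths")
  }
  TRUE
})

#' Multichannel ROI-averaged time series for one subject
#'
#' @slot values channels x time numeric matrix (one row per ROI).
#' @slot trSeconds sampling interval in seconds.
#' @slot roiIds channel labels.
#' @export
setClass("RoiTimeSeriesSet",
  representation(values = "matrix", trSeconds = "numeric", roiIds = "character")
)

setValidity("RoiTimeSeriesSet", function(object) {
  v <- object@values
  if (anyNA(v)) return("time series must not contain missing values")
  if (nrow(v) < 2L) return("need at least 2 channels")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0) {
    return("trSeconds must be a single positive number")
  }
  if (length(object@roiIds) != nrow(v)) {
    return("roiIds must have one label per channel")
  }
  TRUE
})

#' Band-averaged magnitude-squared coherence for all channel pairs
#'
#' @slot w N x N x B array of band-averaged coherence in [0, 1]; each band
#'   slice is symmetric with a zero diagonal.
#' @slot scheme the \linkS4class{FrequencyBandScheme} used.
#' @export
setClass("BandConnectivity",
  representation(w = "array", scheme = "FrequencyBandScheme")
)

setValidity("BandConnectivity", function(object) {
  w <- object@w
  if (length(dim(w)) != 3L || dim(w)[1] != dim(w)[2]) {
    return("w must be an N x N x B array")
  }
  if (dim(w)[3] != nrow(object@scheme@edges)) {
    return("third dimension of w must match the number of bands")
  }
  if (min(w) < -1e-9 || max(w) > 1 + 1e-9) return("coherence must lie in [0, 1]")
  for (b in seq_len(dim(w)[3])) {
    if (max(abs(w[, , b] - t(w[, , b]))) > 1e-9) {
      return("each band slice must be symmetric")
    }
  }
  TRUE
})

#' Surrogate null distribution of band coherence
#'
#' Per-pair, per-band sample mean and standard deviation of coherence
#' computed from IAAFT surrogate pairs, plus Gaussianity diagnostics
#' (sample skewness and excess kurtosis), which are reported but not
#' enforced.
#'
#' @slot mu N x N x B array of null means.
#' @slot sigma N x N x B array of null standard deviations.
#' @slot skewness N x N x B array of per-pair null skewness.
#' @slot kurtosis N x N x B array of per-pair null excess kurtosis.
#' @slot nSurrogates number of surrogate replicates.
#' @export
setClass("SurrogateNull",
  representation(
    mu = "array", sigma = "array", skewness = "array", kurtosis = "array",
    nSurrogates = "integer"
  )
)

setValidity("SurrogateNull", function(object) {
  if (!identical(dim(object@mu), dim(object@sigma))) {
    return("mu and sigma must have identical dimensions")
  }
  if (object@nSurrogates < 2L) return("need at least 2 surrogates")
  TRUE
})

#' Significance-thresholded network for one frequency band
#'
#' Weighted undirected graph whose edge weights are the surrogate z-scores
#' `z_ij = |w_ij - mu_ij| / sigma_ij` that met the retention threshold;
#' entries below the threshold are zero. Isolated nodes are retained.
#'
#' @slot z symmetric N x N matrix of retained z-scores (0 = no edge).
#' @slot band numeric length-2 (low, high) of the band in Hz; may be NA for
#'   synthetic fixtures not tied to a band.
#' @slot threshold the z threshold used for retention.
#' @export
setClass("LayerNetwork",
  representation(z = "matrix", band = "numeric", threshold = "numeric")
)

setValidity("LayerNetwork", function(object) {
  z <- object@z
  if (nrow(z) != ncol(z)) return("z must be square")
  if (max(abs(z - t(z))) > 1e-9) return("z must be symmetric")
  if (any(diag(z) != 0)) return("no self-loops allowed")
  if (length(object@band) != 2L) return("band must be (low, high)")
  nz <- z[z != 0]
  if (length(nz) && length(object@threshold) == 1L && !is.na(object@threshold) &&
      min(nz) < object@threshold - 1e-9) {
    return("all retained weights must be >= threshold")
  }
  TRUE
})

#' Interconnected multiplex network
#'
#' L node-aligned layers over a shared node set plus all-to-all inter-layer
#' coupling: every node is linked to each of its replicas in the other
#' layers with weight D.
#'
#' @slot layers list of \linkS4class{LayerNetwork} over the same node set.
#' @slot D inter-layer coupling weight (>= 0).
#' @export
setClass("MultiplexNetwork", representation(layers = "list", D = "numeric"))

setValidity("MultiplexNetwork", function(object) {
  if (length(object@layers) < 1L) return("need at least one layer")
  if (!all(vapply(object@layers, is, TRUE, class2 = "LayerNetwork"))) {
    return("layers must all be LayerNetwork objects")
  }
  ns <- vapply(object@layers, function(l) nrow(l@z), 1L)
  if (length(unique(ns)) != 1L) return("all layers must share the node set")
  if (length(object@D) != 1L || is.na(object@D) || object@D < 0) {
    return("D must be a single non-negative number")
  }
  TRUE
})

#' Rescaled combinatorial Laplacian (unit-trace density-like matrix)
#'
#' `L = c (S - A)` with S the diagonal strength matrix and
#' `c = 1 / sum(A)`, so the matrix is positive semidefinite with trace 1
#' and its eigenvalues form a probability distribution.
#'
#' @slot matrix the rescaled Laplacian.
#' @slot eigenvalues cached non-negative eigenvalues summing to 1.
#' @export
setClass("RescaledLaplacian",
  representation(matrix = "matrix", eigenvalues = "numeric")
)

setValidity("RescaledLaplacian", function(object) {
  m <- object@matrix
  if (abs(sum(diag(m)) - 1) > 1e-9) return("trace must equal 1")
  if (max(abs(m - t(m))) > 1e-9) return("matrix must be symmetric")
  ev <- object@eigenvalues
  if (length(ev) != nrow(m)) return("one eigenvalue per row expected")
  if (min(ev) < -1e-9) return("eigenvalues must be non-negative")
  if (abs(sum(ev) - 1) > 1e-9) return("eigenvalues must sum to 1")
  TRUE
})

#' Result of the structural layer-reduction analysis
#'
#' @slot distanceMatrix L x L quantum Jensen-Shannon distance matrix.
#' @slot merges merge matrix of the layer dendrogram (hclust convention).
#' @slot heights merge heights of the dendrogram.
#' @slot quality quality-function value at each reduction step; element s+1
#'   corresponds to step s (step 0 = no merge).
#' @slot optimalStep the step maximising the quality function (ties broken
#'   toward the least-reduced partition).
#' @slot layerLabels labels of the input layers.
#' @export
setClass("ReducibilityResult",
  representation(
    distanceMatrix = "matrix", merges = "matrix", heights = "numeric",
    quality = "numeric", optimalStep = "integer", layerLabels = "character"
  )
)

setValidity("ReducibilityResult", function(object) {
  L <- nrow(object@distanceMatrix)
  if (length(object@quality) != L) return("quality must have one entry per step 0..L-1")
  if (object@optimalStep < 0L || object@optimalStep > L - 1L) {
    return("optimalStep out of range")
  }
  TRUE
})

#' Multiplex PageRank centrality profile
#'
#' Stationary distribution of the damped supra-random-walk (0.85 follow /
#' 0.15 teleport). `piStar[j, b]` is the stationary probability of node j's
#' replica in layer b; the per-node profile sums over layers.
#'
#' @slot piStar N x L matrix of node-layer stationary probabilities.
#' @slot D inter-layer coupling weight used.
#' @slot iterations power-iteration steps performed.
#' @slot residual final L1 residual.
#' @export
setClass("CentralityProfile",
  representation(
    piStar = "matrix", D = "numeric", iterations = "integer",
    residual = "numeric"
  )
)

setValidity("CentralityProfile", function(object) {
  p <- object@piStar
  if (abs(sum(p) - 1) > 1e-8) return("stationary probabilities must sum to 1")
  if (min(p) <= 0) return("stationary probabilities must be positive")
  TRUE
})

#' Ground-truth planted multiplex fixture
#'
#' Random layers with known planted hubs, used to test reducibility and
#' centrality without going through signal generation.
#'
#' @slot layers list of unit-weight \linkS4class{LayerNetwork}s.
#' @slot plantedHubs integer node ids of the planted hubs.
#' @export
setClass("GroundTruthMultiplex",
  representation(layers = "list", plantedHubs = "integer")
)

setValidity("GroundTruthMultiplex", function(object) {
  if (length(object@layers) < 1L) return("need at least one layer")
  n <- nrow(object@layers[[1]]@z)
  if (length(object@plantedHubs) &&
      (min(object@plantedHubs) < 1L || max(object@plantedHubs) > n)) {
    return("planted hubs must be valid node ids")
  }
  TRUE
})
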