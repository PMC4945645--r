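# Von Neumann graph entropy, quantum Jensen-Shannon distance and the
# hierarchical layer-reduction analysis.

#' Rescaled combinatorial Laplacian of a weighted graph
#'
#' `L = c (S - A)` with S the diagonal matrix of node strengths and
#' `c = 1 / sum(A)` (the sum over all matrix entries), giving a symmetric
#' positive-semidefinite matrix of unit trace whose eigenvalues form a
#' probability distribution. Rescaling makes the result invariant under a
#' global rescaling of the edge weights.
#'
#' @param adj symmetric non-negative weighted adjacency matrix with at least
#'   one edge, or a \linkS4class{LayerNetwork}.
#' @return a \linkS4class{RescaledLaplacian}.
#' @export
rescaledLaplacian <- function(adj) {
  if (is(adj, "LayerNetwork")) adj <- adj@z
  assertSymmetric(adj, "adjacency")
  if (min(adj) < 0) stop("adjacency must be non-negative")
  tot <- sum(adj)
  if (tot == 0) stop("adjacency has no edges; the rescaled Laplacian is undefined")
  L <- (diag(rowSums(adj)) - adj) / tot
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev[abs(ev) < 1e-12] <- 0
  if (min(ev) < -1e-9) stop("Laplacian unexpectedly not positive semidefinite")
  ev <- pmax(ev, 0)
  ev <- ev / sum(ev)
  new("RescaledLaplacian", matrix = L, eigenvalues = ev)
}

# Shannon entropy in bits of a probability vector, with 0 log2 0 = 0.
spectralEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Von Neumann entropy of a graph (bits)
#'
#' `h = -sum_i lambda_i log2(lambda_i)` over the eigenvalues of the
#' rescaled Laplacian, with `0 log2 0 = 0`. The complete graph K_N attains
#' `log2(N - 1)` exactly; a single edge has entropy 0.
#'
#' @param x a \linkS4class{RescaledLaplacian}, \linkS4class{LayerNetwork}
#'   or adjacency matrix.
#' @return entropy in bits.
#' @export
vonNeumannEntropy <- function(x) {
  if (!is(x, "RescaledLaplacian")) x <- rescaledLaplacian(x)
  spectralEntropy(x@eigenvalues)
}

#' Quantum Jensen-Shannon distance between two layers
#'
#' For rescaled Laplacians `La`, `Lb` and their mixture
#' `Lm = (La + Lb) / 2`, the Jensen-Shannon divergence equals
#' `h(Lm) - (h(La) + h(Lb)) / 2` via the Von Neumann entropy — an identity
#' that avoids matrix logarithms of singular Laplacians. The value lies in
#' [0, 1]; with `sqrtDistance = TRUE` (default) the square root is returned,
#' which is the form satisfying the metric properties (in particular the
#' triangle inequality).
#'
#' @param La,Lb \linkS4class{RescaledLaplacian}s (or layer networks /
#'   adjacency matrices) over the same node set.
#' @param sqrtDistance take the metric square root (default TRUE).
#' @return distance in [0, 1].
#' @export
jsDistance <- function(La, Lb, sqrtDistance = TRUE) {
  if (!is(La, "RescaledLaplacian")) La <- rescaledLaplacian(La)
  if (!is(Lb, "RescaledLaplacian")) Lb <- rescaledLaplacian(Lb)
  if (nrow(La@matrix) != nrow(Lb@matrix)) {
    stop("layers must share the node set (dimension mismatch)")
  }
  Lm <- (La@matrix + Lb@matrix) / 2
  evm <- eigen(Lm, symmetric = TRUE, only.values = TRUE)$values
  evm <- pmax(evm, 0)
  jsd <- spectralEntropy(evm) -
    (spectralEntropy(La@eigenvalues) + spectralEntropy(Lb@eigenvalues)) / 2
  jsd <- min(max(jsd, 0), 1)
  if (sqrtDistance) sqrt(jsd) else jsd
}

#' Pairwise quantum Jensen-Shannon distance matrix of a layer list
#'
#' @param layers list of \linkS4class{LayerNetwork} (or adjacency matrices)
#'   over a shared node set.
#' @param sqrtDistance take the metric square root (default TRUE).
#' @return symmetric L x L matrix with zero diagonal.
#' @export
layerDistanceMatrix <- function(layers, sqrtDistance = TRUE) {
  L <- length(layers)
  lap <- lapply(layers, rescaledLaplacian)
  D <- matrix(0, L, L)
  for (a in seq_len(L - 1L)) {
    for (b in seq.int(a + 1L, L)) {
      D[a, b] <- D[b, a] <- jsDistance(lap[[a]], lap[[b]], sqrtDistance)
    }
  }
  D
}

#' Structural reducibility of a set of layers
#'
#' Runs the layer-reduction analysis: (i) the pairwise quantum
#' Jensen-Shannon distance matrix; (ii) agglomerative hierarchical
#' clustering (Ward linkage) of the layers on that matrix; (iii) at each
#' reduction step the merged groups are replaced by the sum of their
#' adjacency matrices and the quality function
#' `q = 1 - <h> / h_agg` is evaluated, where `<h>` is the mean Von Neumann
#' entropy of the current layer groups and `h_agg` that of the fully
#' aggregated graph. The returned optimal step maximises q; ties are broken
#' toward the least-reduced partition (smallest step), so L identical layers
#' — where q is constant — report step 0. The analysis never uses the
#' inter-layer weight D.
#'
#' @param layers list of at least two \linkS4class{LayerNetwork} over a
#'   shared node set, each with at least one edge.
#' @param layerLabels optional labels (default "layer1", ...).
#' @return a \linkS4class{ReducibilityResult}.
#' @export
reduceLayers <- function(layers, layerLabels = NULL) {
  L <- length(layers)
  if (L < 2L) stop("need at least 2 layers")
  ns <- vapply(layers, nNodes, 1L)
  if (length(unique(ns)) != 1L) stop("layers must share the node set")
  if (is.null(layerLabels)) layerLabels <- paste0("layer", seq_len(L))
  D <- layerDistanceMatrix(layers)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  adjs <- lapply(layers, adjacency)
  hAgg <- vonNeumannEntropy(Reduce(`+`, adjs))
  quality <- numeric(L)
  for (step in 0:(L - 1L)) {
    groups <- stats::cutree(hc, k = L - step)
    hMean <- mean(vapply(unique(groups), function(gid) {
      vonNeumannEntropy(Reduce(`+`, adjs[groups == gid]))
    }, 1))
    quality[step + 1L] <- 1 - hMean / hAgg
  }
  new("ReducibilityResult",
    distanceMatrix = D, merges = hc$merge, heights = hc$height,
    quality = quality, optimalStep = as.integer(which.max(quality) - 1L),
    layerLabels = as.character(layerLabels)
  )
}

#' Group-level statistics of per-subject layer distance matrices
#'
#' For every layer pair and each of two groups, computes the mean `mu` and
#' standard deviation `sigma` of the Jensen-Shannon distance over the
#' group's subjects, the signal-to-noise ratio `snr = mu / sigma` (flagged
#' `NA` where `sigma = 0`), and the relative SNR difference between the two
#' groups `(snr_A - snr_B) / snr_B` (groups in the order of
#' `sort(unique(labels))`).
#'
#' @param distances list of L x L \linkS4class{LayerNetwork} distance
#'   matrices, one per subject.
#' @param labels group label per subject (exactly two distinct values,
#'   at least two subjects each).
#' @return a list with per-group `mu`, `sigma`, `snr` (lists of L x L
#'   matrices keyed by group label) and `relativeDifference`.
#' @export
groupSnr <- function(distances, labels) {
  labels <- as.character(labels)
  if (length(distances) != length(labels)) {
    stop("one label per subject required")
  }
  gs <- sort(unique(labels))
  if (length(gs) != 2L) stop("exactly two groups required")
  if (any(table(labels) < 2L)) stop("need at least 2 subjects per group")
  arr <- simplify2array(distances) # L x L x S
  stat <- function(idx) {
    mu <- apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
    sigma <- apply(arr[, , idx, drop = FALSE], c(1, 2), stats::sd)
    snr <- ifelse(sigma > 0, mu / sigma, NA_real_)
    list(mu = mu, sigma = sigma, snr = snr)
  }
  sA <- stat(labels == gs[1])
  sB <- stat(labels == gs[2])
  list(
    groups = gs,
    mu = stats::setNames(list(sA$mu, sB$mu), gs),
    sigma = stats::setNames(list(sA$sigma, sB$sigma), gs),
    snr = stats::setNames(list(sA$snr, sB$snr), gs),
    relativeDifference = (sA$snr - sB$snr) / sB$snr
  )
}
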