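# Per-layer structural descriptors: degree/strength, assortativity, density,
# Barrat weighted clustering, Louvain modularity, characteristic path length
# and the small-world index against an Erdos-Renyi G(N, m) baseline.

layerToIgraph <- function(layer, weighted = TRUE) {
  igraph::graph_from_adjacency_matrix(
    layer@z,
    mode = "undirected",
    weighted = if (weighted) TRUE else NULL, diag = FALSE
  )
}

#' Basic structural descriptors of a layer
#'
#' @param layer a \linkS4class{LayerNetwork} with at least 2 nodes.
#' @return a list with `meanDegree`, `meanStrength`, `assortativity` (the
#'   degree-degree Pearson coefficient over edge endpoints; `NA` with
#'   attribute `"undefined"` when endpoint degrees have zero variance, e.g.
#'   on a regular graph) and `edgeDensity` (`m / (N (N - 1) / 2)`).
#' @export
basicDescriptors <- function(layer) {
  stopifnot(is(layer, "LayerNetwork"))
  n <- nNodes(layer)
  if (n < 2L) stop("need at least 2 nodes")
  g <- layerToIgraph(layer)
  m <- igraph::ecount(g)
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(assort)) {
    assort <- NA_real_
    attr(assort, "undefined") <- TRUE
  }
  list(
    meanDegree = mean(igraph::degree(g)),
    meanStrength = mean(igraph::strength(g)),
    assortativity = assort,
    edgeDensity = m / (n * (n - 1) / 2)
  )
}

#' Mean Barrat weighted clustering coefficient
#'
#' Per-node weighted clustering (Barrat et al.), averaged over nodes with
#' degree >= 2; nodes of degree < 2 have coefficient 0 and do not enter the
#' average. The coefficient is invariant under global rescaling of the
#' weights.
#'
#' @param layer a \linkS4class{LayerNetwork} with at least 3 nodes.
#' @return mean weighted clustering coefficient.
#' @export
weightedClustering <- function(layer) {
  stopifnot(is(layer, "LayerNetwork"))
  if (nNodes(layer) < 3L) stop("need at least 3 nodes")
  g <- layerToIgraph(layer)
  cc <- igraph::transitivity(g,
    type = "barrat", weights = igraph::E(g)$weight,
    isolates = "NaN"
  )
  deg <- igraph::degree(g)
  keep <- deg >= 2L
  if (!any(keep)) return(0)
  cc[is.nan(cc)] <- 0
  mean(cc[keep])
}

#' Louvain community partition and weighted modularity
#'
#' Greedy multilevel (Louvain) modularity optimisation on the weighted
#' graph; deterministic given `seed`.
#'
#' @param layer a \linkS4class{LayerNetwork} with at least one edge.
#' @param seed integer seed.
#' @return list with `membership` (integer community labels) and
#'   `modularity` (weighted modularity Q of that partition).
#' @export
modularityPartition <- function(layer, seed = 1L) {
  stopifnot(is(layer, "LayerNetwork"))
  g <- layerToIgraph(layer)
  if (igraph::ecount(g) == 0L) stop("modularity undefined on an edgeless graph")
  cl <- withSeed(seed, igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  list(
    membership = as.integer(igraph::membership(cl)),
    modularity = igraph::modularity(g, igraph::membership(cl),
      weights = igraph::E(g)$weight
    )
  )
}

#' Characteristic path length (hop count)
#'
#' Mean unweighted shortest-path length over all connected ordered node
#' pairs; disconnected pairs are excluded from the average and the fraction
#' of connected pairs is reported alongside.
#'
#' @param layer a \linkS4class{LayerNetwork} with at least 2 nodes and one
#'   edge.
#' @return list with `length` (mean hops) and `connectedFraction`.
#' @export
characteristicPathLength <- function(layer) {
  stopifnot(is(layer, "LayerNetwork"))
  if (nNodes(layer) < 2L) stop("need at least 2 nodes")
  g <- layerToIgraph(layer)
  if (igraph::ecount(g) == 0L) stop("path length undefined on an edgeless graph")
  d <- igraph::distances(g, weights = NA)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  list(
    length = mean(off[finite]),
    connectedFraction = mean(finite)
  )
}

# Binary local clustering and pairs-based hop path length used by the
# small-world ratio (degree < 2 nodes count as 0 clustering).
binaryClusteringAndPath <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc[is.nan(cc)] <- 0
  d <- igraph::distances(g, weights = NA)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  list(
    C = mean(cc),
    l = if (any(finite)) mean(off[finite]) else NA_real_,
    connectedFraction = mean(finite)
  )
}

#' Small-world index of a layer
#'
#' `S = (C / C_rand) / (l / l_rand)` where C is the mean binary local
#' clustering coefficient and l the hop-count characteristic path length of
#' the binarised layer, and `C_rand`, `l_rand` are their means over
#' `nRandom` Erdos-Renyi G(N, m) graphs with the same number of nodes and
#' edges. Path lengths always exclude disconnected pairs; if a sizeable part
#' of the random ensemble is disconnected a warning is recorded on the
#' result (attribute `"warning"`).
#'
#' @param layer a \linkS4class{LayerNetwork}.
#' @param nRandom size of the random ensemble (>= 10; default 50).
#' @param seed integer seed for the ensemble.
#' @return the small-world index (numeric scalar).
#' @export
smallWorldIndex <- function(layer, nRandom = 50L, seed = 1L) {
  stopifnot(is(layer, "LayerNetwork"))
  assertCount(nRandom, "nRandom", min = 10L)
  g <- layerToIgraph(layer, weighted = FALSE)
  if (igraph::ecount(g) == 0L) stop("small-world index undefined without edges")
  obs <- binaryClusteringAndPath(g)
  n <- nNodes(layer)
  m <- igraph::ecount(g)
  rand <- withSeed(seed, lapply(seq_len(nRandom), function(i) {
    binaryClusteringAndPath(igraph::sample_gnm(n, m))
  }))
  Cr <- mean(vapply(rand, `[[`, 1, "C"))
  lr <- mean(vapply(rand, `[[`, 1, "l"), na.rm = TRUE)
  connFrac <- mean(vapply(rand, `[[`, 1, "connectedFraction"))
  s <- (obs$C / Cr) / (obs$l / lr)
  if (connFrac < 0.9) {
    attr(s, "warning") <- sprintf(
      "random ensemble largely disconnected (connected pair fraction %.2f); pairs-based path length used",
      connFrac
    )
  }
  s
}

#' All structural descriptors of a layer as one row
#'
#' Convenience wrapper returning a one-row data frame suitable for stacking
#' into a tidy per-(subject, layer) descriptor table.
#'
#' @param layer a \linkS4class{LayerNetwork}.
#' @param seed integer seed for modularity and the small-world ensemble.
#' @param nRandom random-graph ensemble size for the small-world index.
#' @return a one-row data.frame.
#' @export
layerDescriptors <- function(layer, seed = 1L, nRandom = 50L) {
  bd <- basicDescriptors(layer)
  hasEdges <- any(layer@z != 0)
  cpl <- if (hasEdges) characteristicPathLength(layer) else list(length = NA_real_, connectedFraction = 0)
  data.frame(
    meanDegree = bd$meanDegree,
    meanStrength = bd$meanStrength,
    assortativity = as.numeric(bd$assortativity),
    edgeDensity = bd$edgeDensity,
    meanWeightedClustering = if (hasEdges) weightedClustering(layer) else 0,
    modularity = if (hasEdges) modularityPartition(layer, seed)$modularity else NA_real_,
    charPathLength = cpl$length,
    connectedFraction = cpl$connectedFraction,
    smallWorldIndex = if (hasEdges) as.numeric(smallWorldIndex(layer, nRandom, seed)) else NA_real_
  )
}
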