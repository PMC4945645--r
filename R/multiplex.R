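#' Assemble layers into an interconnected multiplex network
#'
#' Couples node-aligned layers by linking every node to each of its replicas
#' in all other layers (all-to-all across layers, not a chain), each
#' inter-layer link carrying weight `D`. Nodes isolated within a layer still
#' get replicas and inter-layer links.
#'
#' @param layers non-empty list of \linkS4class{LayerNetwork} sharing the
#'   node set.
#' @param D inter-layer coupling weight (>= 0).
#' @return a \linkS4class{MultiplexNetwork}.
#' @export
assembleMultiplex <- function(layers, D) {
  if (length(layers) < 1L) stop("need at least one layer")
  ns <- vapply(layers, nNodes, 1L)
  if (length(unique(ns)) != 1L) {
    stop(sprintf(
      "inconsistent node counts across layers: %s",
      paste(unique(ns), collapse = ", ")
    ))
  }
  new("MultiplexNetwork", layers = layers, D = as.numeric(D))
}

#' Supra-adjacency matrix of a multiplex network
#'
#' Flattens the rank-4 adjacency tensor into an `(N L) x (N L)` matrix:
#' diagonal blocks are the layer adjacencies, off-diagonal blocks are
#' `D` times the identity (replica coupling), and entries pairing different
#' nodes in different layers are zero. State ordering is layer-major: state
#' `(b - 1) N + j` is node j's replica in layer b.
#'
#' @param mux a \linkS4class{MultiplexNetwork}.
#' @return a symmetric `(N L) x (N L)` numeric matrix.
#' @export
supraAdjacency <- function(mux) {
  stopifnot(is(mux, "MultiplexNetwork"))
  n <- nNodes(mux)
  L <- nLayers(mux)
  M <- matrix(0, n * L, n * L)
  idx <- function(b) ((b - 1L) * n + 1L):(b * n)
  for (a in seq_len(L)) {
    M[idx(a), idx(a)] <- mux@layers[[a]]@z
    if (mux@D > 0) {
      for (b in seq_len(L)) {
        if (a != b) M[idx(a), idx(b)] <- diag(mux@D, n)
      }
    }
  }
  M
}

#' Aggregate layers by summing their adjacency matrices
#'
#' The fully aggregated single-layer graph: edge weight is the sum of the
#' z-weights across layers, with absent edges contributing zero.
#'
#' @param layers non-empty list of \linkS4class{LayerNetwork} sharing the
#'   node set.
#' @return a \linkS4class{LayerNetwork} whose band is the envelope of the
#'   input bands and whose threshold is NA (sums are not thresholded).
#' @export
aggregateSum <- function(layers) {
  if (length(layers) < 1L) stop("cannot aggregate an empty layer list")
  ns <- vapply(layers, nNodes, 1L)
  if (length(unique(ns)) != 1L) stop("inconsistent node counts across layers")
  zSum <- Reduce(`+`, lapply(layers, adjacency))
  bands <- vapply(layers, function(l) l@band, numeric(2))
  band <- if (anyNA(bands)) c(NA_real_, NA_real_) else range(bands)
  new("LayerNetwork", z = zSum, band = band, threshold = NA_real_)
}

#' Export a supra-adjacency matrix as sparse coordinate triples
#'
#' Writes the non-zero entries of the supra-adjacency as a TSV of
#' (row, col, weight) triples plus a JSON header recording N, L, D and the
#' node/layer labels.
#'
#' @param mux a \linkS4class{MultiplexNetwork}.
#' @param file path of the TSV to write; the JSON header goes to
#'   `paste0(file, ".json")`.
#' @param nodeLabels optional node labels.
#' @return invisibly, the TSV path.
#' @export
writeSupraAdjacency <- function(mux, file, nodeLabels = NULL) {
  M <- supraAdjacency(mux)
  nz <- which(M != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] <= nz[, 2], , drop = FALSE] # upper triangle once
  df <- data.frame(row = nz[, 1], col = nz[, 2], weight = M[nz])
  utils::write.table(df, file,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  hdr <- list(
    n_nodes = nNodes(mux), n_layers = nLayers(mux), D = mux@D,
    node_labels = if (is.null(nodeLabels)) {
      paste0("node", seq_len(nNodes(mux)))
    } else {
      as.character(nodeLabels)
    },
    layer_bands = lapply(mux@layers, function(l) as.numeric(l@band))
  )
  jsonlite::write_json(hdr, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
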