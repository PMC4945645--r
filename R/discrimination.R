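# Two-round random-forest discrimination of centrality profiles, hub
# identification and hub/feature overlap.

#' Default random-forest parameters
#'
#' 700 trees, at most 5 terminal nodes per tree, 2 candidate variables per
#' split — small trees in a large forest, suited to many weak features.
#'
#' @return a list with `ntree`, `maxnodes`, `mtry`.
#' @export
defaultRfParams <- function() list(ntree = 700L, maxnodes = 5L, mtry = 2L)

# profiles: list of CentralityProfile or numeric vectors -> subjects x nodes
profileMatrix <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (is(p, "CentralityProfile")) nodeProfile(p) else as.numeric(p)
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("profiles must share the node set")
  }
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("roi", seq_len(ncol(X)))
  X
}

fitForest <- function(X, y, rfParams, seed) {
  rng <- apply(X, 2, function(v) max(v) - min(v))
  if (all(rng == 0)) {
    stop("all features are constant across subjects; nothing to classify")
  }
  withSeed(seed, randomForest::randomForest(
    x = X, y = y,
    ntree = rfParams$ntree,
    maxnodes = min(rfParams$maxnodes, nrow(X)), # a tree cannot exceed n leaves
    mtry = min(rfParams$mtry, ncol(X))
  ))
}

#' Leave-one-out Gini-importance feature ranking
#'
#' Fits one random forest per left-out subject, ranks the features within
#' each fold by mean decrease in Gini importance (rank 1 = most important,
#' ties get average ranks) and sums the ranks over folds: lower summed rank
#' = more consistently discriminative. The left-out subject's prediction is
#' recorded, giving first-round LOO accuracy as a by-product.
#'
#' @param profiles list of \linkS4class{CentralityProfile} (or numeric
#'   profile vectors), one per subject.
#' @param labels group label per subject (two classes, >= 4 subjects).
#' @param rfParams list with `ntree`, `maxnodes`, `mtry` (see
#'   [defaultRfParams()]).
#' @param seed master seed; per-fold seeds are derived from it.
#' @return a list of class `FeatureRanking` with `summedRank` (named numeric),
#'   `nFolds`, `predictions`, `labels` and `accuracy`.
#' @export
looFeatureRanking <- function(profiles, labels, rfParams = defaultRfParams(),
                              seed = 1L) {
  X <- profileMatrix(profiles)
  y <- factor(as.character(labels))
  if (nlevels(y) != 2L) stop("exactly two classes required")
  if (nrow(X) < 4L) stop("need at least 4 subjects for leave-one-out ranking")
  if (nrow(X) != length(y)) stop("one label per subject required")
  n <- nrow(X)
  summed <- stats::setNames(numeric(ncol(X)), colnames(X))
  preds <- character(n)
  for (s in seq_len(n)) {
    if (nlevels(droplevels(y[-s])) != 2L) {
      stop("training folds must contain both classes")
    }
    rf <- fitForest(X[-s, , drop = FALSE], droplevels(y[-s]), rfParams,
      seed = deriveSeed(seed, s)
    )
    gini <- rf$importance[, "MeanDecreaseGini"]
    summed <- summed + rank(-gini, ties.method = "average")
    preds[s] <- as.character(stats::predict(rf, X[s, , drop = FALSE]))
  }
  structure(
    list(
      summedRank = summed, nFolds = n, predictions = preds,
      labels = as.character(y), accuracy = mean(preds == as.character(y))
    ),
    class = "FeatureRanking"
  )
}

# Indices of the top-k features by summed rank (ties -> lowest index).
topFeatures <- function(ranking, topK) {
  order(ranking$summedRank, seq_along(ranking$summedRank))[seq_len(topK)]
}

#' Second-round LOO classification on the top-k ranked features
#'
#' Leave-one-out classification restricted to the `topK` features with the
#' smallest summed Gini rank. Accuracy, sensitivity, specificity and
#' precision are assembled from the pooled LOO predictions, averaged over
#' `nRepeats` master seeds to tame forest stochasticity; the confusion
#' counts reported are those of the first repeat. The second factor level of
#' the labels is treated as the positive class.
#'
#' @inheritParams looFeatureRanking
#' @param ranking a `FeatureRanking` from [looFeatureRanking()].
#' @param topK number of features to keep (1..N).
#' @param nRepeats master-seed repeats to average over (default 5).
#' @return a list of class `ClassificationReport` with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `confusion`, `topK`,
#'   `features`, `seed`.
#' @export
topkClassification <- function(profiles, labels, ranking, topK,
                               rfParams = defaultRfParams(), seed = 1L,
                               nRepeats = 5L) {
  X <- profileMatrix(profiles)
  y <- factor(as.character(labels))
  if (nlevels(y) != 2L) stop("exactly two classes required")
  if (topK < 1L || topK > ncol(X)) stop("topK must lie in 1..N")
  keep <- sort(topFeatures(ranking, topK)) # node order, so k = N is exactly round one
  Xk <- X[, keep, drop = FALSE]
  n <- nrow(Xk)
  accs <- numeric(nRepeats)
  firstPreds <- NULL
  for (r in seq_len(nRepeats)) {
    preds <- character(n)
    for (s in seq_len(n)) {
      rf <- fitForest(Xk[-s, , drop = FALSE], droplevels(y[-s]), rfParams,
        seed = deriveSeed(seed, (r - 1L) * n + s)
      )
      preds[s] <- as.character(stats::predict(rf, Xk[s, , drop = FALSE]))
    }
    accs[r] <- mean(preds == as.character(y))
    if (r == 1L) firstPreds <- preds
  }
  pos <- levels(y)[2L]
  neg <- levels(y)[1L]
  tp <- sum(firstPreds == pos & y == pos)
  tn <- sum(firstPreds == neg & y == neg)
  fp <- sum(firstPreds == pos & y == neg)
  fn <- sum(firstPreds == neg & y == pos)
  structure(
    list(
      accuracy = mean(accs), accuracyBySeed = accs,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
      positiveClass = pos, topK = as.integer(topK),
      features = colnames(X)[keep], seed = as.integer(seed)
    ),
    class = "ClassificationReport"
  )
}

#' Scan the inter-layer weight D and the feature count k
#'
#' For each D in `dGrid`, recomputes the multiplex centrality profile of
#' every subject, runs the LOO Gini ranking and, for each k in `kGrid`, the
#' second-round classification. Returns the (D, k) with the best accuracy
#' (ties broken toward smaller k, then smaller D) plus the full report grid.
#'
#' @param layersBySubject list (one element per subject) of layer lists.
#' @param labels group label per subject.
#' @param dGrid numeric grid of inter-layer weights (non-empty).
#' @param kGrid integer grid of feature counts (non-empty).
#' @inheritParams looFeatureRanking
#' @param nRepeats repeats passed to [topkClassification()] (default 1 for
#'   scan speed; refit the chosen point with more repeats if needed).
#' @return list with `bestD`, `bestK`, `bestReport`, `grid` (data.frame of
#'   D, k, accuracy, sensitivity, specificity, precision).
#' @export
scanHyperparameters <- function(layersBySubject, labels, dGrid, kGrid,
                                rfParams = defaultRfParams(), seed = 1L,
                                nRepeats = 1L) {
  if (length(dGrid) < 1L || length(kGrid) < 1L) stop("grids must be non-empty")
  rows <- list()
  best <- NULL
  for (D in dGrid) {
    profiles <- lapply(layersBySubject, function(ls) {
      multiplexPageRank(assembleMultiplex(ls, D))
    })
    ranking <- looFeatureRanking(profiles, labels, rfParams, seed)
    for (k in sort(as.integer(kGrid))) {
      rp <- topkClassification(profiles, labels, ranking, k, rfParams,
        seed = seed, nRepeats = nRepeats
      )
      rows[[length(rows) + 1L]] <- data.frame(
        D = D, k = k, accuracy = rp$accuracy,
        sensitivity = rp$sensitivity, specificity = rp$specificity,
        precision = rp$precision
      )
      if (is.null(best) || rp$accuracy > best$report$accuracy + 1e-12 ||
        (abs(rp$accuracy - best$report$accuracy) <= 1e-12 &&
          (k < best$k || (k == best$k && D < best$D)))) {
        best <- list(D = D, k = k, report = rp)
      }
    }
  }
  list(
    bestD = best$D, bestK = best$k, bestReport = best$report,
    grid = do.call(rbind, rows)
  )
}

#' Identify hub nodes from group-averaged centrality
#'
#' Averages the per-node profile over the group's subjects and takes the
#' `round(fraction * N)` highest nodes (round half up; e.g. 5% of 264 nodes
#' gives 13 hubs). Ties at the cutoff are resolved toward the lowest node
#' id; a fully tied profile is flagged with attribute `"fullyTied"`.
#'
#' @param groupProfiles list of \linkS4class{CentralityProfile} (or numeric
#'   profiles) of one group's subjects.
#' @param fraction top fraction to keep (default 0.05).
#' @return integer vector of hub node ids (class `HubSet` attributes:
#'   `fraction`, `meanProfile`).
#' @export
identifyHubs <- function(groupProfiles, fraction = 0.05) {
  if (length(groupProfiles) < 1L) stop("need at least one profile")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  X <- profileMatrix(groupProfiles)
  avg <- colMeans(X)
  n <- length(avg)
  nh <- floor(fraction * n + 0.5) # round half up
  if (nh < 1L) stop("fraction * N < 1: no hubs can be selected")
  ord <- order(-avg, seq_len(n))
  hubs <- sort(ord[seq_len(nh)])
  attr(hubs, "fraction") <- fraction
  attr(hubs, "meanProfile") <- avg
  if (max(avg) - min(avg) < 1e-15) attr(hubs, "fullyTied") <- TRUE
  class(hubs) <- c("HubSet", class(hubs))
  hubs
}

#' Jaccard index of two node sets
#'
#' `|a intersect b| / |a union b|`; two empty sets give 0 by convention
#' (flagged with attribute `"bothEmpty"`).
#'
#' @param a,b vectors of node ids.
#' @return fraction in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) {
    out <- 0
    attr(out, "bothEmpty") <- TRUE
    return(out)
  }
  length(intersect(a, b)) / length(u)
}
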