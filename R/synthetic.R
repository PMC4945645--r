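# Synthetic cohorts: ROI time series with planted band-specific coupling,
# planted multiplex fixtures, and cohort CSV/JSON round-tripping.

#' Configuration of a synthetic labelled cohort
#'
#' Defines two groups of subjects whose ROI time series share band-limited
#' latent signals. Each group effect adds one latent — white noise whose
#' Fourier coefficients outside the target band are zeroed, standardised to
#' unit sd — to every member node, scaled by the coupling strength; every
#' node additionally receives independent Gaussian noise. Hub nodes of a
#' group share a broadband latent with all other nodes (at strength
#' `hubStrength` for the hub and `hubStrength * hubLeak` elsewhere), so they
#' become densely connected in every band.
#'
#' @param nSubjectsPerGroup subjects per group (default 10).
#' @param nRois number of ROIs/channels (default 40; the full-scale design
#'   uses 264).
#' @param nTimepoints time points per subject (>= 64; default 180, i.e.
#'   6 min at TR = 2 s).
#' @param trSeconds sampling interval (default 2, Nyquist 0.25 Hz).
#' @param bandScheme numeric (fLow, fHigh, width) in Hz (default
#'   0.01-0.25 Hz in 0.02 Hz bands, i.e. 12 bands).
#' @param groupEffects list of effects, each a list with fields `group`
#'   (label), `band` (1-based band index), `nodes` (integer node ids) and
#'   `strength` (coupling in [0, 1]).
#' @param hubNodes named list of integer node-id vectors per group label
#'   (may be empty).
#' @param hubStrength coupling of a hub to its broadband latent (in [0, 1]).
#' @param hubLeak fraction of `hubStrength` received by non-hub nodes.
#' @param noiseSd sd of the independent noise added everywhere (default 1).
#' @param seed master integer seed.
#' @param groupLabels the two group labels (default "A", "B").
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nSubjectsPerGroup = 10L, nRois = 40L,
                            nTimepoints = 180L, trSeconds = 2,
                            bandScheme = c(0.01, 0.25, 0.02),
                            groupEffects = list(), hubNodes = list(),
                            hubStrength = 0.8, hubLeak = 0.35,
                            noiseSd = 1, seed = 42L,
                            groupLabels = c("A", "B")) {
  assertCount(nSubjectsPerGroup, "nSubjectsPerGroup")
  assertCount(nRois, "nRois", min = 2L)
  assertCount(nTimepoints, "nTimepoints", min = 64L)
  if (trSeconds <= 0) stop("trSeconds must be positive")
  if (length(groupLabels) != 2L || anyDuplicated(groupLabels)) {
    stop("exactly two distinct group labels required")
  }
  scheme <- makeBandScheme(bandScheme[1], bandScheme[2], bandScheme[3])
  for (ef in groupEffects) {
    if (!all(c("group", "band", "nodes", "strength") %in% names(ef))) {
      stop("each group effect needs fields group, band, nodes, strength")
    }
    if (!ef$group %in% groupLabels) stop("effect group must be a group label")
    if (ef$band < 1L || ef$band > nBands(scheme)) {
      stop(sprintf("effect band index %d outside the band scheme", ef$band))
    }
    if (length(ef$nodes) == 0L) stop("effect has an empty coupled node set")
    if (min(ef$nodes) < 1L || max(ef$nodes) > nRois) {
      stop("effect node ids must be valid indices <= nRois")
    }
    if (ef$strength < 0 || ef$strength > 1) {
      stop("coupling strengths must lie in [0, 1]")
    }
  }
  for (g in names(hubNodes)) {
    h <- hubNodes[[g]]
    if (length(h) && (min(h) < 1L || max(h) > nRois)) {
      stop("hub node ids must be valid indices <= nRois")
    }
  }
  if (hubStrength < 0 || hubStrength > 1) stop("hubStrength must lie in [0, 1]")
  structure(
    list(
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      nRois = as.integer(nRois), nTimepoints = as.integer(nTimepoints),
      trSeconds = trSeconds, bandScheme = bandScheme, scheme = scheme,
      groupEffects = groupEffects, hubNodes = hubNodes,
      hubStrength = hubStrength, hubLeak = hubLeak,
      noiseSd = noiseSd, seed = as.integer(seed), groupLabels = groupLabels
    ),
    class = "SyntheticConfig"
  )
}

# Band-limited unit-sd latent: white noise with Fourier bins outside
# [low, high) zeroed (exact band confinement, no filter ringing).
bandLimitedLatent <- function(nT, trSeconds, low, high) {
  x <- stats::rnorm(nT)
  f <- stats::fft(x)
  freqs <- (seq_len(nT) - 1L) / (nT * trSeconds)
  # map second half to negative-frequency magnitudes
  fold <- pmin(freqs, 1 / trSeconds - freqs)
  keep <- fold >= low - 1e-12 & fold < high - 1e-12
  f[!keep] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / nT
  s <- stats::sd(y)
  if (s == 0) stop("band too narrow for the series length: empty latent")
  y / s
}

#' Generate one subject's ROI time series
#'
#' White Gaussian noise per ROI plus, for each configured effect matching
#' the subject's group, a shared band-limited latent added to the member
#' nodes scaled by the coupling strength; hub latents as described in
#' [syntheticConfig()]. Deterministic given `seed`.
#'
#' @param cfg a `SyntheticConfig`.
#' @param group one of the two group labels.
#' @param seed integer seed for this subject.
#' @return a \linkS4class{RoiTimeSeriesSet}.
#' @export
generateSubjectTimeSeries <- function(cfg, group, seed) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (!group %in% cfg$groupLabels) {
    stop(sprintf("unknown group label '%s'", group))
  }
  withSeed(seed, {
    n <- cfg$nRois
    nT <- cfg$nTimepoints
    x <- matrix(stats::rnorm(n * nT, sd = cfg$noiseSd), n, nT)
    for (ef in cfg$groupEffects) {
      if (ef$group != group) next
      e <- cfg$scheme@edges[ef$band, ]
      lat <- bandLimitedLatent(nT, cfg$trSeconds, e[1], e[2])
      x[ef$nodes, ] <- x[ef$nodes, ] +
        rep(ef$strength * lat, each = length(ef$nodes))
    }
    hubs <- cfg$hubNodes[[group]]
    if (length(hubs)) {
      fb <- range(cfg$scheme@edges)
      for (h in hubs) {
        lat <- bandLimitedLatent(nT, cfg$trSeconds, fb[1], fb[2])
        x[h, ] <- x[h, ] + cfg$hubStrength * lat
        others <- setdiff(seq_len(n), h)
        x[others, ] <- x[others, ] +
          rep(cfg$hubStrength * cfg$hubLeak * lat, each = length(others))
      }
    }
    roiTimeSeriesSet(x, cfg$trSeconds)
  })
}

#' Generate a labelled synthetic cohort
#'
#' `2 * nSubjectsPerGroup` subjects, the first half in the first group;
#' subject s uses the derived seed `cfg$seed + s`, so subjects are
#' independent but the cohort is reproducible.
#'
#' @param cfg a `SyntheticConfig`.
#' @return a list of class `LabeledCohort` with `subjects` (list of
#'   \linkS4class{RoiTimeSeriesSet}), `labels` (character), `seeds` and
#'   `config`.
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  ns <- cfg$nSubjectsPerGroup
  labels <- rep(cfg$groupLabels, each = ns)
  seeds <- vapply(seq_along(labels), function(s) deriveSeed(cfg$seed, s), 1L)
  subjects <- lapply(seq_along(labels), function(s) {
    generateSubjectTimeSeries(cfg, labels[s], seeds[s])
  })
  structure(
    list(subjects = subjects, labels = labels, seeds = seeds, config = cfg),
    class = "LabeledCohort"
  )
}

#' Generate a planted multiplex fixture
#'
#' Each layer is an independent Erdos-Renyi G(n, p) graph with unit weights;
#' each planted hub is additionally connected, in every layer, to
#' `extraDegree` uniformly chosen non-neighbours. The inter-layer weight is
#' left unset — assign it with [assembleMultiplex()].
#'
#' @param nNodes node count.
#' @param nLayers layer count (1 is allowed: degenerate single-layer case).
#' @param hubNodes integer ids of planted hubs (may be empty).
#' @param extraDegree extra connections per hub per layer (< nNodes).
#' @param baseEdgeProb edge probability in (0, 1).
#' @param seed integer seed.
#' @return a \linkS4class{GroundTruthMultiplex}.
#' @export
generatePlantedMultiplex <- function(nNodes, nLayers, hubNodes = integer(0),
                                     extraDegree = 0L, baseEdgeProb = 0.1,
                                     seed = 1L) {
  assertCount(nNodes, "nNodes", min = 2L)
  assertCount(nLayers, "nLayers")
  if (baseEdgeProb <= 0 || baseEdgeProb >= 1) {
    stop("baseEdgeProb must lie strictly between 0 and 1")
  }
  hubNodes <- as.integer(hubNodes)
  if (length(hubNodes) && max(hubNodes) > nNodes) {
    stop("hub node id exceeds nNodes")
  }
  if (extraDegree >= nNodes) stop("hub extra-degree must be < nNodes")
  layers <- withSeed(seed, lapply(seq_len(nLayers), function(l) {
    g <- igraph::sample_gnp(nNodes, baseEdgeProb)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    for (h in hubNodes) {
      nonNb <- setdiff(which(A[h, ] == 0), h)
      add <- if (length(nonNb) <= extraDegree) nonNb else {
        sample(nonNb, extraDegree)
      }
      A[h, add] <- 1
      A[add, h] <- 1
    }
    new("LayerNetwork",
      z = A, band = c(NA_real_, NA_real_),
      threshold = NA_real_
    )
  }))
  new("GroundTruthMultiplex", layers = layers, plantedHubs = hubNodes)
}

#' Write a cohort as per-subject CSVs plus a JSON manifest
#'
#' One CSV per subject (rows = ROIs, columns = time points, full double
#' precision) and a `manifest.json` recording labels, per-subject seeds,
#' TR and the generating configuration, so [readCohort()] round-trips
#' exactly.
#'
#' @param cohort a `LabeledCohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "LabeledCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("subject_%03d.csv", seq_along(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    v <- cohort$subjects[[s]]@values
    con <- file(file.path(dir, files[s]), "w")
    writeLines(vapply(seq_len(nrow(v)), function(i) {
      paste(sprintf("%.17g", v[i, ]), collapse = ",")
    }, ""), con)
    close(con)
  }
  cfg <- cohort$config
  manifest <- list(
    files = files, labels = cohort$labels, seeds = cohort$seeds,
    tr_seconds = cfg$trSeconds,
    config = cfg[setdiff(names(cfg), "scheme")]
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing the per-subject CSVs and manifest.json.
#' @return a `LabeledCohort`.
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
  subjects <- lapply(manifest$files, function(f) {
    rows <- readLines(file.path(dir, f))
    v <- do.call(rbind, lapply(strsplit(rows, ","), as.numeric))
    roiTimeSeriesSet(v, as.numeric(manifest$tr_seconds))
  })
  cfgList <- manifest$config
  cfg <- syntheticConfig(
    nSubjectsPerGroup = cfgList$nSubjectsPerGroup, nRois = cfgList$nRois,
    nTimepoints = cfgList$nTimepoints, trSeconds = cfgList$trSeconds,
    bandScheme = cfgList$bandScheme,
    groupEffects = lapply(cfgList$groupEffects, as.list),
    hubNodes = lapply(cfgList$hubNodes, as.integer),
    hubStrength = cfgList$hubStrength, hubLeak = cfgList$hubLeak,
    noiseSd = cfgList$noiseSd, seed = cfgList$seed,
    groupLabels = cfgList$groupLabels
  )
  structure(
    list(
      subjects = subjects, labels = manifest$labels,
      seeds = manifest$seeds, config = cfg
    ),
    class = "LabeledCohort"
  )
}
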