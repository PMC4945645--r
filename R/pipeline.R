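# Configuration-driven orchestration of the full analysis:
# signals -> band layers -> multiplex -> descriptors -> reducibility ->
# centrality -> discrimination.

pipelineDefaults <- function() {
  list(
    input_dir = NULL, # cohort manifest dir; NULL -> synthetic
    synthetic = list(), # overrides passed to syntheticConfig()
    band_low = 0.01, band_high = 0.25, band_width = 0.02,
    n_surrogates = 100L, z_threshold = 3,
    D = 24.7708, d_grid = NULL, k_grid = NULL,
    rf_ntree = 700L, rf_maxnodes = 5L, rf_mtry = 2L, rf_repeats = 1L,
    top_k = 5L, hub_fraction = 0.05,
    n_random_graphs = 50L,
    output_dir = "pipeline_out", seed = 1L, log_level = "info"
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, fills in documented defaults
#' (bands 0.01-0.25 Hz in 0.02 Hz steps, z threshold 3, 700-tree forests),
#' rejects unknown keys and collects all validation errors rather than
#' stopping at the first.
#'
#' @param path configuration file, or a named list already in memory.
#' @return the validated configuration list (class `PipelineConfig`); errors
#'   raise a condition whose message lists every offending field.
#' @export
validateConfig <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("config parse error in ", path, ": ", conditionMessage(e))
    })
  }
  defs <- pipelineDefaults()
  errs <- character(0)
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(defs, cfg[setdiff(names(cfg), unknown)])
  num <- function(field, min = -Inf, strict = FALSE) {
    v <- merged[[field]]
    bad <- !is.numeric(v) || length(v) != 1L || is.na(v) ||
      (strict && v <= min) || (!strict && v < min)
    if (bad) errs <<- c(errs, sprintf("field '%s' must be a number %s %g",
      field, if (strict) ">" else ">=", min))
  }
  num("band_low", 0)
  num("band_high", 0, strict = TRUE)
  num("band_width", 0, strict = TRUE)
  num("n_surrogates", 20)
  num("z_threshold", 0, strict = TRUE)
  num("D", 0)
  num("top_k", 1)
  num("seed")
  if (!is.null(merged$d_grid) && (!is.numeric(merged$d_grid) || any(merged$d_grid < 0))) {
    errs <- c(errs, "field 'd_grid' must be non-negative numbers")
  }
  if (merged$hub_fraction <= 0 || merged$hub_fraction >= 1) {
    errs <- c(errs, "field 'hub_fraction' must lie in (0, 1)")
  }
  if (!merged$log_level %in% c("debug", "info", "warn", "quiet")) {
    errs <- c(errs, "field 'log_level' must be one of debug/info/warn/quiet")
  }
  if (is.numeric(merged$band_low) && is.numeric(merged$band_high) &&
      is.numeric(merged$band_width) && merged$band_width > 0) {
    tryCatch(makeBandScheme(merged$band_low, merged$band_high, merged$band_width),
      error = function(e) errs <<- c(errs, conditionMessage(e))
    )
  }
  if (length(errs)) {
    stop("invalid pipeline configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(merged) <- c("PipelineConfig", "list")
  merged
}

pipeLog <- function(cfg, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[cfg$log_level]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

stageTry <- function(stage, subject = NULL, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.null(subject)) stage else sprintf("%s (subject %s)", stage, subject)
    stop(sprintf("stage '%s' failed: %s", where, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full multiplex connectivity pipeline
#'
#' Executes all stages on a cohort (synthetic by default, or read from an
#' on-disk manifest): band-specific surrogate-thresholded layers per
#' subject, per-layer structural descriptors, layer reducibility and group
#' SNR of the layer distances, multiplex plus full-band/typical-band
#' centrality profiles, and two-round random-forest discrimination. Every
#' intermediate artifact is written under `output_dir` (TSV edge lists,
#' GraphML, CSV tables, JSON reports, Newick dendrograms) together with a
#' machine-readable `summary.json` recording versions, seeds and timings.
#' Reruns with the same configuration and seed are bit-identical for the
#' deterministic stages.
#'
#' @param cfg a `PipelineConfig` from [validateConfig()], a path to one, or
#'   a named list of overrides.
#' @return invisibly, the run summary list.
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- validateConfig(cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    package_version = as.character(utils::packageVersion("multiplexfc")),
    r_version = R.version.string, seed = cfg$seed, stages = list()
  )
  tic <- function() Sys.time()
  stamp <- function(stage, t0) {
    summary$stages[[stage]] <<- list(
      status = "completed", seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }

  # -- stage 1: cohort ------------------------------------------------------
  t0 <- tic()
  cohort <- stageTry("simulate", NULL, {
    if (!is.null(cfg$input_dir)) {
      readCohort(cfg$input_dir)
    } else {
      sc <- do.call(syntheticConfig, utils::modifyList(
        list(seed = cfg$seed), cfg$synthetic
      ))
      generateCohort(sc)
    }
  })
  pipeLog(cfg, "info", sprintf("cohort: %d subjects", length(cohort$subjects)))
  stamp("simulate", t0)

  scheme <- makeBandScheme(cfg$band_low, cfg$band_high, cfg$band_width)
  nSub <- length(cohort$subjects)

  # -- stage 2: band layers -------------------------------------------------
  t0 <- tic()
  layerDir <- file.path(out, "layers")
  dir.create(layerDir, showWarnings = FALSE)
  layersBySubject <- vector("list", nSub)
  for (s in seq_len(nSub)) {
    bl <- stageTry("connect", s, buildLayers(
      cohort$subjects[[s]], scheme,
      nSurrogates = cfg$n_surrogates, zThreshold = cfg$z_threshold,
      seed = deriveSeed(cfg$seed, 1000L + s)
    ))
    layersBySubject[[s]] <- bl$layers
    writeLayerEdgeLists(bl$layers, file.path(layerDir, sprintf("subject_%03d", s)))
    pipeLog(cfg, "debug", sprintf("subject %d: layers built", s))
  }
  stamp("connect", t0)

  # -- stage 3: descriptors -------------------------------------------------
  t0 <- tic()
  desc <- stageTry("descriptors", NULL, do.call(rbind, lapply(seq_len(nSub), function(s) {
    do.call(rbind, lapply(seq_along(layersBySubject[[s]]), function(b) {
      ly <- layersBySubject[[s]][[b]]
      row <- if (any(ly@z != 0)) {
        layerDescriptors(ly,
          seed = deriveSeed(cfg$seed, 2000L + s * 20L + b),
          nRandom = cfg$n_random_graphs
        )
      } else {
        layerDescriptors0()
      }
      cbind(data.frame(subject = s, label = cohort$labels[s], band = b), row)
    }))
  })))
  utils::write.csv(desc, file.path(out, "layer_descriptors.csv"), row.names = FALSE)
  stamp("descriptors", t0)

  # -- stage 4: reducibility ------------------------------------------------
  t0 <- tic()
  distList <- vector("list", nSub)
  qualList <- vector("list", nSub)
  okRed <- logical(nSub)
  for (s in seq_len(nSub)) {
    res <- tryCatch(reduceLayers(layersBySubject[[s]]), error = function(e) e)
    if (inherits(res, "error")) {
      pipeLog(cfg, "warn", sprintf(
        "subject %d: reducibility skipped (%s)", s, conditionMessage(res)
      ))
      next
    }
    okRed[s] <- TRUE
    distList[[s]] <- res@distanceMatrix
    qualList[[s]] <- res@quality
    utils::write.csv(res@distanceMatrix,
      file.path(out, sprintf("jsd_subject_%03d.csv", s)),
      row.names = FALSE
    )
    writeDendrogramNewick(res, file.path(out, sprintf("dendrogram_%03d.nwk", s)))
  }
  if (any(okRed)) {
    qual <- do.call(rbind, qualList[okRed])
    utils::write.csv(
      data.frame(subject = which(okRed), label = cohort$labels[okRed], qual),
      file.path(out, "quality_trajectories.csv"),
      row.names = FALSE
    )
  }
  snr <- NULL
  if (sum(okRed) >= 4L && length(unique(cohort$labels[okRed])) == 2L &&
      all(table(cohort$labels[okRed]) >= 2L)) {
    snr <- groupSnr(distList[okRed], cohort$labels[okRed])
    utils::write.csv(snr$relativeDifference,
      file.path(out, "snr_relative_difference.csv"),
      row.names = FALSE
    )
  }
  stamp("reduce", t0)

  # -- stage 5: centrality --------------------------------------------------
  t0 <- tic()
  profiles <- vector("list", nSub)
  fullBand <- vector("list", nSub)
  typicalBand <- vector("list", nSub)
  for (s in seq_len(nSub)) {
    profiles[[s]] <- stageTry("centrality", s, multiplexPageRank(
      assembleMultiplex(layersBySubject[[s]], cfg$D)
    ))
    fullBand[[s]] <- stageTry("centrality", s, singleLayerPageRank(
      conventionalBandNetwork(cohort$subjects[[s]], cfg$band_low, cfg$band_high,
        nSurrogates = cfg$n_surrogates, zThreshold = cfg$z_threshold,
        seed = deriveSeed(cfg$seed, 1000L + s)
      )
    ))
    typicalBand[[s]] <- stageTry("centrality", s, singleLayerPageRank(
      conventionalBandNetwork(cohort$subjects[[s]], 0.01, 0.1,
        nSurrogates = cfg$n_surrogates, zThreshold = cfg$z_threshold,
        seed = deriveSeed(cfg$seed, 1000L + s)
      )
    ))
  }
  writeProfilesCsv(profiles, file.path(out, "multiplex_profiles.csv"))
  writeProfilesCsv(fullBand, file.path(out, "fullband_profiles.csv"))
  writeProfilesCsv(typicalBand, file.path(out, "typicalband_profiles.csv"))
  profCor <- vapply(seq_len(nSub), function(s) c(
    multiplexVsFull = as.numeric(compareProfiles(profiles[[s]], fullBand[[s]])),
    multiplexVsTypical = as.numeric(compareProfiles(profiles[[s]], typicalBand[[s]])),
    fullVsTypical = as.numeric(compareProfiles(fullBand[[s]], typicalBand[[s]]))
  ), numeric(3))
  utils::write.csv(
    cbind(data.frame(subject = seq_len(nSub)), t(profCor)),
    file.path(out, "profile_correlations.csv"),
    row.names = FALSE
  )
  stamp("centrality", t0)

  # -- stage 6: discrimination ----------------------------------------------
  t0 <- tic()
  rfParams <- list(
    ntree = cfg$rf_ntree, maxnodes = cfg$rf_maxnodes, mtry = cfg$rf_mtry
  )
  clf <- NULL
  clfRun <- function() {
    if (!is.null(cfg$d_grid) && !is.null(cfg$k_grid)) {
      scan <- scanHyperparameters(layersBySubject, cohort$labels,
        cfg$d_grid, cfg$k_grid, rfParams,
        seed = deriveSeed(cfg$seed, 5000L),
        nRepeats = cfg$rf_repeats
      )
      utils::write.csv(scan$grid, file.path(out, "classification_grid.csv"),
        row.names = FALSE
      )
      list(
        bestD = scan$bestD, bestK = scan$bestK,
        report = scan$bestReport[setdiff(names(scan$bestReport), "features")]
      )
    } else {
      ranking <- looFeatureRanking(profiles, cohort$labels, rfParams,
        seed = deriveSeed(cfg$seed, 5000L)
      )
      rp <- topkClassification(profiles, cohort$labels, ranking,
        topK = min(cfg$top_k, nNodes(profiles[[1]])), rfParams,
        seed = deriveSeed(cfg$seed, 6000L), nRepeats = cfg$rf_repeats
      )
      list(
        bestD = cfg$D, bestK = rp$topK, firstRoundAccuracy = ranking$accuracy,
        report = rp[setdiff(names(rp), "features")]
      )
    }
  }
  clf <- tryCatch(stageTry("classify", NULL, clfRun()), error = function(e) {
    # degenerate cohorts (e.g. all networks empty) cannot be classified
    if (!grepl("constant across subjects", conditionMessage(e))) stop(e)
    pipeLog(cfg, "warn", conditionMessage(e))
    list(skipped = conditionMessage(e))
  })
  jsonlite::write_json(clf, file.path(out, "classification_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  # hubs per group on the multiplex profiles
  gs <- sort(unique(cohort$labels))
  # guarantee at least one hub on small node sets
  effFrac <- max(cfg$hub_fraction, 1.01 / nNodes(profiles[[1]]))
  hubs <- lapply(gs, function(g) {
    as.integer(identifyHubs(profiles[cohort$labels == g], effFrac))
  })
  names(hubs) <- gs
  hubs$jaccard <- as.numeric(jaccardIndex(hubs[[1]], hubs[[2]]))
  jsonlite::write_json(hubs, file.path(out, "hubs.json"),
    auto_unbox = TRUE, digits = NA
  )
  stamp("classify", t0)

  # -- stage 7: summary -----------------------------------------------------
  t0 <- tic()
  summary$n_subjects <- nSub
  summary$n_bands <- nBands(scheme)
  summary$accuracy <- clf$report$accuracy
  summary$hub_jaccard_between_groups <- hubs$jaccard
  stamp("summary", t0)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  pipeLog(cfg, "info", sprintf(
    "pipeline complete: %d stages", length(summary$stages)
  ))
  invisible(summary)
}

# all-NA descriptor row for an empty layer
layerDescriptors0 <- function() {
  data.frame(
    meanDegree = 0, meanStrength = 0, assortativity = NA_real_,
    edgeDensity = 0, meanWeightedClustering = 0, modularity = NA_real_,
    charPathLength = NA_real_, connectedFraction = 0,
    smallWorldIndex = NA_real_
  )
}

#' Write a layer list as weighted edge lists plus GraphML and a JSON sidecar
#'
#' One TSV (node_i, node_j, z) and one GraphML file per band, plus a JSON
#' sidecar with the band edges.
#'
#' @param layers list of \linkS4class{LayerNetwork}.
#' @param prefix path prefix; files become `<prefix>_band<b>.tsv` / `.graphml`.
#' @return invisibly, the sidecar path.
#' @export
writeLayerEdgeLists <- function(layers, prefix) {
  for (b in seq_along(layers)) {
    z <- layers[[b]]@z
    nz <- which(z != 0 & upper.tri(z), arr.ind = TRUE)
    utils::write.table(
      data.frame(node_i = nz[, 1], node_j = nz[, 2], z = z[nz]),
      sprintf("%s_band%02d.tsv", prefix, b),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    igraph::write_graph(layerToIgraph(layers[[b]]),
      sprintf("%s_band%02d.graphml", prefix, b),
      format = "graphml"
    )
  }
  sidecar <- paste0(prefix, "_bands.json")
  jsonlite::write_json(
    lapply(layers, function(l) as.numeric(l@band)), sidecar,
    auto_unbox = FALSE, digits = NA
  )
  invisible(sidecar)
}

#' Write centrality profiles as a tidy CSV
#'
#' One row per (subject, node) with per-layer stationary probabilities and
#' the per-node profile.
#'
#' @param profiles list of \linkS4class{CentralityProfile}.
#' @param file output CSV path.
#' @return invisibly, `file`.
#' @export
writeProfilesCsv <- function(profiles, file) {
  df <- do.call(rbind, lapply(seq_along(profiles), function(s) {
    p <- profiles[[s]]
    d <- data.frame(subject = s, node = seq_len(nNodes(p)))
    pi <- p@piStar
    colnames(pi) <- paste0("pi_layer", seq_len(ncol(pi)))
    cbind(d, pi, profile = nodeProfile(p))
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export a reducibility dendrogram as a Newick string
#'
#' Serialises the layer-merge dendrogram over the layer labels.
#'
#' @param res a \linkS4class{ReducibilityResult}.
#' @param file output path (optional).
#' @return invisibly, the Newick string.
#' @export
writeDendrogramNewick <- function(res, file = NULL) {
  hc <- structure(
    list(
      merge = res@merges, height = res@heights,
      labels = res@layerLabels, order = seq_along(res@layerLabels)
    ),
    class = "hclust"
  )
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(file)) writeLines(nwk, file)
  invisible(nwk)
}
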