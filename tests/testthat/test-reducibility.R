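test_that("rescaled Laplacian has unit trace and known spectra", {
  for (w in c(0.5, 1, 3)) {
    lap <- rescaledLaplacian(matrix(c(0, w, w, 0), 2))
    expect_equal(sort(lap@eigenvalues), c(0, 1), tolerance = 1e-12)
  }
  k5 <- rescaledLaplacian(completeGraph(5))
  expect_equal(sum(diag(k5@matrix)), 1, tolerance = 1e-12)
  expect_equal(sort(k5@eigenvalues), c(0, rep(1 / 4, 4)), tolerance = 1e-12)
  expect_gte(min(k5@eigenvalues), 0)
  expect_error(rescaledLaplacian(matrix(0, 3, 3)), "no edges")
})

test_that("Von Neumann entropy attains its closed forms on complete graphs", {
  for (n in c(3, 5, 9, 17)) {
    expect_equal(vonNeumannEntropy(completeGraph(n)), log2(n - 1), tolerance = 1e-10)
  }
  expect_equal(vonNeumannEntropy(matrix(c(0, 1, 1, 0), 2)), 0)
  # invariance under global weight rescaling
  z <- randomWeightedGraph(8, 0.5, seed = 70)
  expect_equal(vonNeumannEntropy(z), vonNeumannEntropy(5.5 * z), tolerance = 1e-10)
})

test_that("Jensen-Shannon distance is symmetric, zero on identical layers and
           matches the matrix-log oracle", {
  k5 <- completeGraph(5)
  c5 <- cycleGraph(5)
  expect_equal(jsDistance(k5, k5), 0)
  expect_equal(jsDistance(k5, c5), jsDistance(c5, k5))
  oracle <- sqrt(oracleJSD(oracleRescaledLaplacian(k5), oracleRescaledLaplacian(c5)))
  expect_equal(jsDistance(k5, c5), oracle, tolerance = 1e-8)
  # more well-conditioned (connected) random instances
  for (sd in 1:5) {
    a <- randomWeightedGraph(7, 0.7, seed = 80 + sd)
    b <- randomWeightedGraph(7, 0.7, seed = 90 + sd)
    expect_equal(
      jsDistance(a, b),
      sqrt(oracleJSD(oracleRescaledLaplacian(a), oracleRescaledLaplacian(b))),
      tolerance = 1e-8
    )
  }
  expect_error(jsDistance(k5, completeGraph(6)), "dimension")
})

test_that("the square-rooted divergence satisfies the triangle inequality", {
  set.seed(8)
  for (i in 1:20) {
    g <- lapply(1:3, function(k) randomWeightedGraph(10, 0.4, seed = 300 + 3 * i + k))
    d12 <- jsDistance(g[[1]], g[[2]])
    d13 <- jsDistance(g[[1]], g[[3]])
    d23 <- jsDistance(g[[2]], g[[3]])
    expect_lte(d12, d13 + d23 + 1e-9)
    expect_lte(d13, d12 + d23 + 1e-9)
    expect_lte(d23, d12 + d13 + 1e-9)
  }
})

test_that("layer reduction keeps informative layers and merges duplicates first", {
  # independent dense random layers: optimum at no reduction
  layers <- lapply(1:4, function(i) mkLayer(1 * (randomWeightedGraph(30, 0.3, seed = 400 + i) > 0)))
  res <- reduceLayers(layers)
  expect_equal(res@optimalStep, 0L)
  expect_length(res@quality, 4L)

  # duplicated pair merges first; merging duplicates costs no quality
  base <- mkLayer(1 * (randomWeightedGraph(20, 0.25, seed = 410) > 0))
  indep1 <- mkLayer(1 * (randomWeightedGraph(20, 0.25, seed = 411) > 0))
  indep2 <- mkLayer(1 * (randomWeightedGraph(20, 0.25, seed = 412) > 0))
  res2 <- reduceLayers(list(base, base, indep1, indep2))
  expect_equal(sort(res2@merges[1, ]), c(-2L, -1L))
  expect_gte(res2@quality[2], res2@quality[1] - 1e-9)

  # identical copies: constant quality, tie-break to no reduction
  res3 <- reduceLayers(list(base, base, base))
  expect_lt(max(res3@quality) - min(res3@quality), 1e-9)
  expect_equal(res3@optimalStep, 0L)
  expect_true(all(res3@distanceMatrix < 1e-6))

  expect_error(reduceLayers(list(base)), "at least 2")
})

test_that("group SNR statistics flag degenerate pairs and match hand arithmetic", {
  d1 <- matrix(c(0, .2, .2, 0), 2)
  d2 <- matrix(c(0, .3, .3, 0), 2)
  d3 <- matrix(c(0, .4, .4, 0), 2)
  d4 <- matrix(c(0, .5, .5, 0), 2)
  out <- groupSnr(list(d1, d2, d3, d4), c("A", "A", "B", "B"))
  expect_equal(out$mu[["A"]][1, 2], 0.25)
  expect_equal(out$sigma[["A"]][1, 2], sd(c(.2, .3)))
  expect_equal(out$snr[["A"]][1, 2], 0.25 / sd(c(.2, .3)))
  expect_equal(
    out$relativeDifference[1, 2],
    (0.25 / sd(c(.2, .3)) - 0.45 / sd(c(.4, .5))) / (0.45 / sd(c(.4, .5)))
  )
  # identical subjects within a group: sigma = 0 -> undefined SNR
  same <- groupSnr(list(d1, d1, d2, d2), c("A", "A", "B", "B"))
  expect_true(is.na(same$snr[["A"]][1, 2]))
  expect_error(groupSnr(list(d1, d2, d3), c("A", "A", "B")), "at least 2")
})

test_that("group differences planted in one band surface in that layer's distances", {
  # both groups share coupling in all bands; only band 3 differs in strength
  nb <- 6L
  mkCfg <- function(s3) {
    syntheticConfig(
      nSubjectsPerGroup = 6L, nRois = 10L, nTimepoints = 180L,
      bandScheme = c(0.01, 0.25, 0.04),
      groupEffects = c(
        lapply(seq_len(nb), function(b) {
          list(group = "A", band = b, nodes = 1:5, strength = if (b == 3L) 0.5 else 0.8)
        }),
        lapply(seq_len(nb), function(b) {
          list(group = "B", band = b, nodes = 1:5, strength = if (b == 3L) s3 else 0.8)
        })
      ),
      seed = 505L
    )
  }
  coh <- generateCohort(mkCfg(1.0))
  scheme <- makeBandScheme(0.01, 0.25, 0.04)
  dists <- lapply(seq_along(coh$subjects), function(s) {
    ls <- buildLayers(coh$subjects[[s]], scheme,
      nSurrogates = 20, seed = 600 + s
    )$layers
    layerDistanceMatrix(ls)
  })
  out <- groupSnr(dists, coh$labels)
  rel <- abs(out$relativeDifference)
  rel[!is.finite(rel)] <- 0
  peak <- which(rel == max(rel), arr.ind = TRUE)[1, ]
  expect_true(3L %in% peak)
})
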