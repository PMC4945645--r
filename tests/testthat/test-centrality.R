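test_that("transition matrix is row-stochastic with the documented structure", {
  # single complete layer on 3 nodes: follow term spreads 1/2 per neighbour
  mux <- assembleMultiplex(list(mkLayer(completeGraph(3))), D = 0)
  R <- transitionMatrix(mux)
  expect_equal(R[1, 2], 0.85 / 2 + 0.15 / 3)
  expect_equal(rowSums(R), rep(1, 3))

  # dangling state: D = 0 and node isolated in layer 2 -> uniform row
  z2 <- matrix(0, 3, 3)
  z2[1, 2] <- z2[2, 1] <- 1
  mux2 <- assembleMultiplex(list(mkLayer(completeGraph(3)), mkLayer(z2)), D = 0)
  R2 <- transitionMatrix(mux2)
  expect_equal(R2[6, ], rep(1 / 6, 6)) # node 3 in layer 2
  expect_equal(rowSums(R2), rep(1, 6))

  # random multiplex: rows sum to one within 1e-12
  gt <- generatePlantedMultiplex(5, 3, baseEdgeProb = 0.4, seed = 3)
  R3 <- transitionMatrix(assembleMultiplex(gt@layers, D = 2))
  expect_lt(max(abs(rowSums(R3) - 1)), 1e-12)
})

test_that("multiplex PageRank matches a dense eigendecomposition", {
  fixtures <- list(
    list(n = 6, L = 2, D = 1), list(n = 10, L = 3, D = 0.5),
    list(n = 20, L = 5, D = 24.7708), list(n = 5, L = 2, D = 0)
  )
  for (fx in fixtures) {
    gt <- generatePlantedMultiplex(fx$n, fx$L, baseEdgeProb = 0.3, seed = fx$n + fx$L)
    mux <- assembleMultiplex(gt@layers, fx$D)
    cp <- multiplexPageRank(mux)
    R <- transitionMatrix(mux)
    expect_equal(as.numeric(cp@piStar), oracleStationary(R), tolerance = 1e-8)
    expect_equal(sum(cp@piStar), 1, tolerance = 1e-10)
    expect_true(all(cp@piStar > 0))
  }
})

test_that("stationarity mass is conserved along the power iteration", {
  gt <- generatePlantedMultiplex(8, 2, baseEdgeProb = 0.3, seed = 5)
  R <- transitionMatrix(assembleMultiplex(gt@layers, 1))
  p <- rep(1 / 16, 16)
  for (i in 1:50) {
    p <- as.numeric(t(R) %*% p)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("symmetric fixtures give closed-form centralities", {
  # 1 node, 1 layer (dangling): profile is 1
  one <- new("LayerNetwork", z = matrix(0, 1, 1), band = c(NA_real_, NA_real_),
    threshold = NA_real_)
  expect_equal(nodeProfile(multiplexPageRank(assembleMultiplex(list(one), 0))), 1)

  # L identical complete layers: uniform by node-permutation symmetry
  ls <- lapply(1:3, function(i) mkLayer(completeGraph(7)))
  p <- nodeProfile(multiplexPageRank(assembleMultiplex(ls, D = 3)))
  expect_equal(p, rep(1 / 7, 7), tolerance = 1e-9)

  # 2-node weighted chain: alternates between the nodes -> uniform
  p2 <- nodeProfile(singleLayerPageRank(mkLayer(matrix(c(0, 2.7, 2.7, 0), 2))))
  expect_equal(p2, c(0.5, 0.5), tolerance = 1e-9)

  # star: hub strictly most central, matches the eigen oracle
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  cp <- singleLayerPageRank(mkLayer(star))
  expect_gt(nodeProfile(cp)[1], max(nodeProfile(cp)[-1]))
  expect_equal(as.numeric(cp@piStar),
    oracleStationary(transitionMatrix(assembleMultiplex(list(mkLayer(star)), 0))),
    tolerance = 1e-9
  )
})

test_that("identical layers lump exactly onto a self-loop node chain", {
  # replica symmetry: the multiplex of L identical layers is equivalent to a
  # node walk with self-loop weight (L-1)D at every node; as D -> 0 this
  # approaches the single-layer PageRank (for D > 0 the two differ).
  l1 <- mkLayer(randomWeightedGraph(12, 0.3, seed = 33))
  A <- adjacency(l1)
  for (D in c(0.5, 5)) {
    s <- rowSums(A)
    cD <- 2 * D
    P <- 0.85 * A / (s + cD)
    diag(P) <- 0.85 * cD / (s + cD)
    P <- P + 0.15 / 12
    pi <- rep(1 / 12, 12)
    for (i in 1:5000) pi <- as.numeric(t(P) %*% pi)
    pL <- nodeProfile(multiplexPageRank(assembleMultiplex(list(l1, l1, l1), D)))
    expect_equal(pL, pi, tolerance = 1e-8)
  }
  p0 <- nodeProfile(multiplexPageRank(assembleMultiplex(list(l1, l1, l1), 1e-9)))
  expect_equal(p0, nodeProfile(singleLayerPageRank(l1)), tolerance = 1e-6)
})

test_that("planted hubs attain the top multiplex PageRank", {
  hits <- vapply(1:20, function(sd) {
    gt <- generatePlantedMultiplex(20, 3,
      hubNodes = 1L, extraDegree = 10L,
      baseEdgeProb = 0.15, seed = sd
    )
    p <- nodeProfile(multiplexPageRank(assembleMultiplex(gt@layers, 1)))
    which.max(p) == 1L
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("near-complete random layers give a near-uniform profile", {
  gt <- generatePlantedMultiplex(15, 3, baseEdgeProb = 0.95, seed = 2)
  p <- nodeProfile(multiplexPageRank(assembleMultiplex(gt@layers, 2)))
  expect_lt(max(abs(p - 1 / 15)), 0.01)
})

test_that("profile comparison is a Spearman rank correlation", {
  set.seed(9)
  a <- runif(10)
  b <- runif(10)
  expect_equal(compareProfiles(a, a), 1)
  expect_equal(compareProfiles(a, max(a) - a + min(a)), -1)
  expect_equal(compareProfiles(a, b), oracleSpearman(a, b))
  con <- compareProfiles(rep(1, 10), a)
  expect_true(is.na(con))
  expect_true(isTRUE(attr(con, "undefined")))
  expect_error(compareProfiles(a, b[1:5]), "node set")
})
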