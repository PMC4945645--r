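test_that("basic descriptors match closed forms and a brute-force oracle", {
  k4 <- basicDescriptors(mkLayer(completeGraph(4)))
  expect_equal(k4$edgeDensity, 1)
  expect_equal(k4$meanDegree, 3)
  expect_equal(k4$meanStrength, 3)

  p4 <- basicDescriptors(mkLayer(pathGraph(4)))
  expect_equal(p4$edgeDensity, 0.5)
  expect_equal(p4$assortativity, -0.5)
  expect_equal(p4$assortativity, oracleDegreeAssortativity(pathGraph(4)))

  cyc <- basicDescriptors(mkLayer(cycleGraph(5)))
  expect_true(is.na(cyc$assortativity))
  expect_true(isTRUE(attr(cyc$assortativity, "undefined")))

  set.seed(31)
  z <- randomWeightedGraph(9, 0.4, seed = 31)
  got <- basicDescriptors(mkLayer(z))
  expect_equal(got$assortativity, oracleDegreeAssortativity(z), tolerance = 1e-9)
  expect_equal(got$meanStrength, mean(rowSums(z)))
})

test_that("Barrat weighted clustering matches the edge-by-edge formula", {
  expect_equal(weightedClustering(mkLayer(completeGraph(3))), 1)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(weightedClustering(mkLayer(star)), 0)
  for (sd in 1:5) {
    z <- randomWeightedGraph(8, 0.5, seed = 40 + sd)
    expect_equal(
      weightedClustering(mkLayer(z)),
      oracleBarrat(z)$meanOverDeg2,
      tolerance = 1e-9
    )
  }
  # invariance under global weight rescaling
  z <- randomWeightedGraph(8, 0.5, seed = 46)
  expect_equal(weightedClustering(mkLayer(z)), weightedClustering(mkLayer(7 * z)),
    tolerance = 1e-12
  )
})

test_that("Louvain modularity recovers planted cliques and satisfies the formula", {
  two <- matrix(0, 10, 10)
  two[1:5, 1:5] <- completeGraph(5)
  two[6:10, 6:10] <- completeGraph(5)
  two[5, 6] <- two[6, 5] <- 1
  got <- modularityPartition(mkLayer(two), seed = 3)
  expect_length(unique(got$membership), 2L)
  expect_equal(got$membership[1:5], rep(got$membership[1], 5))
  expect_gt(got$modularity, 0.3)
  # the clique partition beats a sample of random partitions on this instance
  set.seed(5)
  for (i in 1:50) {
    rnd <- sample(1:2, 10, replace = TRUE)
    expect_gte(got$modularity, oracleModularity(two, rnd) - 1e-12)
  }

  kk <- modularityPartition(mkLayer(completeGraph(6)), seed = 1)
  expect_equal(kk$modularity, 0)

  z <- randomWeightedGraph(10, 0.4, seed = 50)
  got2 <- modularityPartition(mkLayer(z), seed = 2)
  expect_equal(got2$modularity, oracleModularity(z, got2$membership), tolerance = 1e-9)
  expect_error(modularityPartition(mkLayer(matrix(0, 4, 4))), "edgeless")
})

test_that("characteristic path length enumerates connected pairs only", {
  expect_equal(characteristicPathLength(mkLayer(completeGraph(5)))$length, 1)
  p4 <- characteristicPathLength(mkLayer(pathGraph(4)))
  expect_equal(p4$length, 5 / 3)
  expect_equal(p4$connectedFraction, 1)
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  got <- characteristicPathLength(mkLayer(two))
  expect_equal(got$length, 1)
  expect_equal(got$connectedFraction, 2 / 6)
})

test_that("small-world index is ~1 on random graphs and large on ring lattices", {
  # self-consistency: an Erdos-Renyi layer scores about 1
  s <- mean(vapply(1:20, function(sd) {
    set.seed(200 + sd)
    g <- igraph::sample_gnp(50, 0.15)
    as.numeric(smallWorldIndex(
      mkLayer(as.matrix(igraph::as_adjacency_matrix(g))),
      nRandom = 20, seed = sd
    ))
  }, 1))
  expect_gt(s, 0.8)
  expect_lt(s, 1.2)

  # Watts-Strogatz ring: high clustering, short paths
  set.seed(7)
  ws <- igraph::sample_smallworld(1, 100, 3, 0.05)
  sw <- smallWorldIndex(mkLayer(as.matrix(igraph::as_adjacency_matrix(ws))),
    nRandom = 20, seed = 9
  )
  expect_gt(as.numeric(sw), 1.5)

  # complete graph: both ratios are exactly 1
  expect_equal(as.numeric(smallWorldIndex(mkLayer(completeGraph(8)), nRandom = 10, seed = 1)), 1)
})

test_that("density, clustering and modularity are weight-scale invariant", {
  z <- randomWeightedGraph(10, 0.35, seed = 60)
  a <- mkLayer(z)
  b <- mkLayer(3.7 * z)
  expect_equal(basicDescriptors(a)$edgeDensity, basicDescriptors(b)$edgeDensity)
  pa <- modularityPartition(a, seed = 4)
  pb <- modularityPartition(b, seed = 4)
  expect_equal(pa$modularity, pb$modularity, tolerance = 1e-9)
})
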