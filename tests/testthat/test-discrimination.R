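# Small forests keep the unit tests fast; the acceptance suite exercises the
# 700-tree default configuration.
fastRf <- list(ntree = 200L, maxnodes = 5L, mtry = 2L)

signalCohort <- function(n = 20L, p = 20L, shift = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  labels <- rep(c("A", "B"), each = n / 2)
  X[, 1] <- X[, 1] * 0.05 + ifelse(labels == "B", shift, 0)
  list(profiles = lapply(seq_len(n), function(i) X[i, ]), labels = labels)
}

test_that("a label-aligned feature attains the minimal summed Gini rank", {
  hits <- vapply(1:20, function(sd) {
    co <- signalCohort(seed = 700 + sd)
    rk <- looFeatureRanking(co$profiles, co$labels, fastRf, seed = sd)
    which.min(rk$summedRank) == 1L
  }, TRUE)
  expect_gte(sum(hits), 18L)
})

test_that("degenerate cohorts are rejected", {
  co <- signalCohort(n = 8)
  expect_error(looFeatureRanking(co$profiles[c(1, 5)], co$labels[c(1, 5)], fastRf), "at least 4")
  expect_error(looFeatureRanking(co$profiles, rep("A", 8), fastRf), "two classes")
})

test_that("top-k second round separates a separable cohort and keeps its books", {
  co <- signalCohort(n = 12, p = 10, shift = 4, seed = 3)
  rk <- looFeatureRanking(co$profiles, co$labels, fastRf, seed = 4)
  rp <- topkClassification(co$profiles, co$labels, rk,
    topK = 5, fastRf,
    seed = 5, nRepeats = 1
  )
  expect_equal(rp$accuracy, 1.0)
  expect_equal(sum(rp$confusion), 12)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)

  # k = N with the same master seed reproduces the first-round predictions
  rpAll <- topkClassification(co$profiles, co$labels, rk,
    topK = 10, fastRf,
    seed = 4, nRepeats = 1
  )
  expect_equal(rpAll$accuracy, rk$accuracy)
  expect_error(
    topkClassification(co$profiles, co$labels, rk, topK = 99, fastRf),
    "1..N"
  )
})

test_that("leave-one-out predictions never see the held-out subject", {
  # duplicate a subject with a flipped label: if the duplicate leaked into
  # training, both copies would be predicted 'correctly'; without leakage the
  # twin (same features, opposite label) makes that impossible for both.
  co <- signalCohort(n = 10, p = 6, shift = 4, seed = 6)
  profiles <- c(co$profiles, co$profiles[1])
  labels <- c(co$labels, setdiff(unique(co$labels), co$labels[1]))
  rk <- looFeatureRanking(profiles, labels, fastRf, seed = 7)
  correct <- rk$predictions == rk$labels
  expect_false(correct[1] && correct[11])
})

test_that("label permutation yields no optimistic skill", {
  co <- signalCohort(n = 16, p = 12, shift = 3, seed = 8)
  set.seed(9)
  accs <- vapply(1:20, function(i) {
    perm <- sample(co$labels)
    looFeatureRanking(co$profiles, perm, fastRf, seed = 900 + i)$accuracy
  }, 1)
  # LOO on balanced cohorts is pessimistically biased, so the null centres at
  # or below chance; what must not happen is spurious skill above it.
  expect_lt(mean(accs), 0.5 + 2 * sd(accs) / sqrt(length(accs)))
})

test_that("hub identification takes the rounded top fraction with stable ties", {
  profiles264 <- lapply(1:4, function(i) {
    set.seed(i)
    p <- runif(264)
    p / sum(p)
  })
  hubs <- identifyHubs(profiles264, 0.05)
  expect_length(hubs, 13L) # round(0.05 * 264) = 13
  avg <- colMeans(do.call(rbind, profiles264))
  expect_setequal(as.integer(hubs), order(-avg)[1:13])

  tied <- identifyHubs(list(rep(1 / 20, 20)), 0.25)
  expect_equal(as.integer(tied), 1:5)
  expect_true(isTRUE(attr(tied, "fullyTied")))
  expect_error(identifyHubs(list(rep(1 / 20, 20)), 0.01), "no hubs")

  # planted multiplex hub lands in the hub set
  gt <- generatePlantedMultiplex(20, 3,
    hubNodes = 4L, extraDegree = 12L,
    baseEdgeProb = 0.15, seed = 11
  )
  prof <- multiplexPageRank(assembleMultiplex(gt@layers, 1))
  expect_true(4L %in% as.integer(identifyHubs(list(prof), 0.1)))
})

test_that("Jaccard index matches set arithmetic", {
  a <- 1:30
  b <- c(1:3, 101:127) # 30 elements, 3 shared
  expect_equal(round(jaccardIndex(a, b), 3), 0.053)
  b2 <- c(1:13, 101:117) # 30 elements, 13 shared
  expect_equal(round(jaccardIndex(a, b2), 3), 0.277)
  expect_equal(jaccardIndex(a, a), 1)
  empty <- jaccardIndex(integer(0), integer(0))
  expect_equal(as.numeric(empty), 0)
  expect_true(isTRUE(attr(empty, "bothEmpty")))
  set.seed(13)
  for (i in 1:10) {
    x <- sample(50, 20)
    y <- sample(50, 15)
    expect_equal(jaccardIndex(x, y), length(intersect(x, y)) / length(union(x, y)))
    expect_equal(jaccardIndex(x, y), jaccardIndex(y, x))
  }
})

test_that("the (D, k) scan returns the accuracy-maximising grid point", {
  gts <- lapply(1:8, function(i) {
    generatePlantedMultiplex(8, 2,
      hubNodes = if (i <= 4) 1L else 2L,
      extraDegree = 5L, baseEdgeProb = 0.2, seed = 40 + i
    )@layers
  })
  labels <- rep(c("A", "B"), each = 4)
  one <- scanHyperparameters(gts, labels,
    dGrid = 1, kGrid = 3, fastRf,
    seed = 15
  )
  expect_equal(one$bestD, 1)
  expect_equal(one$bestK, 3L)
  expect_equal(nrow(one$grid), 1L)

  grid <- scanHyperparameters(gts, labels,
    dGrid = c(0.5, 2), kGrid = c(2, 4),
    fastRf, seed = 15
  )
  expect_equal(max(grid$grid$accuracy), grid$bestReport$accuracy)
  expect_gte(grid$bestReport$accuracy, one$grid$accuracy[1] - 1)
  expect_error(scanHyperparameters(gts, labels, numeric(0), 3), "non-empty")
})
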