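test_that("genome graph construction gives path-graph counts", {
  g <- buildGenome(rep(1000L, 20))
  expect_identical(nodeCount(g), 20000L)
  expect_identical(edgeCount(g), 19980L)
  expect_identical(liveEdgeCount(g), 19980L)
  g1 <- buildGenome(1L)
  expect_identical(nodeCount(g1), 1L)
  expect_identical(edgeCount(g1), 0L)
  expect_identical(blockSizes(g1), 1L)
  g2 <- buildGenome(c(3L, 2L))
  expect_identical(nodeCount(g2), 5L)
  expect_identical(edgeCount(g2), 3L)
  expect_identical(sort(blockSizes(g2)), c(2L, 3L))
  expect_error(buildGenome(integer()), "positive integers")
  expect_error(buildGenome(c(5L, 0L)), "positive integers")
})

test_that("block sizes are the connected components and conserve genes", {
  g <- buildGenome(5L)
  g@liveEdges[2L] <- FALSE
  expect_identical(sort(blockSizes(g)), c(2L, 3L))
  gAll <- buildGenome(c(4L, 3L))
  gAll@liveEdges[] <- FALSE
  expect_identical(blockSizes(gAll), rep(1L, 7L))
  # random removals: sizes match igraph components and conserve the total
  set.seed(11)
  for (i in 1:15) {
    sizes <- sample(1:12, sample(1:4, 1), replace = TRUE)
    g <- buildGenome(sizes)
    if (edgeCount(g) > 0L)
      g@liveEdges <- runif(edgeCount(g)) > 0.4
    got <- sort(blockSizes(g))
    # independent oracle: igraph connected components
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))
    ends <- lapply(seq_along(sizes), function(ch) {
      if (sizes[ch] < 2L) return(NULL)
      left <- offsets[ch] + seq_len(sizes[ch] - 1L)
      cbind(left, left + 1L)
    })
    ends <- do.call(rbind, ends)
    live <- if (is.null(ends)) NULL else ends[g@liveEdges, , drop = FALSE]
    ig <- igraph::graph_from_edgelist(
      matrix(as.numeric(live), ncol = 2), directed = FALSE)
    ig <- igraph::add_vertices(ig, sum(sizes) - igraph::vcount(ig))
    expect_identical(got, sort(as.integer(
      igraph::components(ig)$csize)))
    expect_identical(sum(got), sum(sizes))
  }
})

test_that("spot assignment follows the two-state Markov chain", {
  m <- HotspotModel(0.5, 0.01, rHC = 1, rCH = 1)
  g <- buildGenome(50L)
  sp <- assignSpots(g, m, seed = 3)
  expect_true(all(abs(diff(sp@labels)) == 1L))  # strict alternation
  # empirical hotspot fraction approaches the stationary law (piH = 1/6)
  mStat <- HotspotModel(0.5, 0.01, rHC = 0.05, rCH = 0.01)
  gBig <- buildGenome(rep(20001L, 5))  # 1e5 edges
  spBig <- assignSpots(gBig, mStat, seed = 4)
  expect_equal(mean(spBig@labels == 1L), 1 / 6, tolerance = 0.12)
  # nearly absorbing coldspots: hotspots essentially absent
  mCold <- HotspotModel(0.5, 0.01, rHC = 0.5, rCH = 1e-6)
  spCold <- assignSpots(buildGenome(10001L), mCold, seed = 5)
  expect_lt(mean(spCold@labels == 1L), 1e-3)
})

test_that("superposition sampling matches literal per-edge minima", {
  # 100-edge toy chromosome; compare removed-edge-count distributions of
  # the fast path and the stepwise reference oracle
  m <- OneCutModel(0.2)
  tMax <- 0.5
  nrep <- 1200L
  fast <- integer(nrep); slow <- integer(nrep)
  set.seed(71)
  for (i in seq_len(nrep)) {
    g <- buildGenome(101L)
    fast[i] <- 100L - liveEdgeCount(simulateBreakage(g, m, tMax))
    slow[i] <- 100L -
      liveEdgeCount(syntenyDecay:::.simulateBreakageStepwise(g, m, tMax))
  }
  bins <- c(-Inf, 4:14, Inf)
  tabF <- table(cut(fast, bins))
  tabS <- table(cut(slow, bins))
  p <- suppressWarnings(chisq.test(rbind(tabF, tabS))$p.value)
  expect_gt(p, 1e-3)
  # both match the Poisson-thinning mean: 100 * (1 - exp(-0.1))
  expect_equal(mean(fast), 100 * -expm1(-0.1), tolerance = 0.02)
  expect_equal(mean(slow), 100 * -expm1(-0.1), tolerance = 0.02)
})

test_that("removed-edge counts follow per-edge Poisson thinning", {
  # 20x1000 genome, kappa = 0.1, t = 0.25: E[removed] = 19980 (1 - e^-0.025)
  m <- OneCutModel(0.1)
  nrep <- 40L
  removed <- numeric(nrep)
  set.seed(19)
  g0 <- buildGenome(rep(1000L, 20))
  for (i in seq_len(nrep))
    removed[i] <- edgeCount(g0) - liveEdgeCount(simulateBreakage(g0, m, 0.25))
  expected <- 19980 * -expm1(-0.025)
  sem <- sd(removed) / sqrt(nrep)
  expect_lt(abs(mean(removed) - expected), 3 * sem + 1e-9)
})

test_that("two-cut partner bookkeeping respects chromosome boundaries", {
  # theta -> infinity: partner is always the adjacent edge
  g <- buildGenome(10L)
  set.seed(2)
  g2 <- syntenyDecay:::.applyCuts(g, TwoCutModel(0.1, 500), 3L)
  expect_identical(which(!g2@liveEdges), c(3L, 4L))
  # an initial cut at the last edge of chromosome 1 never removes a
  # chromosome-2 edge, whatever the span
  gAB <- buildGenome(c(5L, 5L))
  set.seed(3)
  for (i in 1:30) {
    gCut <- syntenyDecay:::.applyCuts(gAB, TwoCutModel(0.1, 0.05), 4L)
    expect_true(all(gCut@liveEdges[gAB@edgeChromosome == 2L]))
  }
  # removed edges never exceed twice the number of initial events
  set.seed(4)
  gBig <- buildGenome(rep(500L, 4))
  events <- sample.int(edgeCount(gBig), 300L, replace = TRUE)
  gDone <- syntenyDecay:::.applyCuts(gBig, TwoCutModel(0.1, 0.5), events)
  expect_lte(edgeCount(gBig) - liveEdgeCount(gDone), 2L * 300L)
})

test_that("zero elapsed time leaves the genome intact", {
  g <- buildGenome(c(100L, 50L))
  gSame <- simulateBreakage(g, OneCutModel(0.5), tMax = 0, seed = 1)
  expect_identical(sort(blockSizes(gSame)), sort(chromosomeSizes(g)))
  expect_error(simulateBreakage(g, HotspotModel(0.5, 0.01, 0.1, 0.1), 0.1),
               "SpotAssignment")
  expect_error(
    simulateBreakage(g, CombinedModel(0.1, 0.1, 0.5), 0.1),
    "one_cut, two_cut and hotspot")
})

test_that("ensembles conserve genes and summarize replicate variation", {
  ens <- runEnsemble(OneCutModel(0.1), tMax = 0.25, replicates = 1L,
                     chromosomeSizes = rep(200L, 4), seed = 9)
  expect_true(all(ensembleSd(ens) == 0))  # single replicate: no spread
  ens3 <- runEnsemble(TwoCutModel(0.1, 0.5), tMax = 0.25, replicates = 3L,
                      chromosomeSizes = rep(200L, 4), seed = 10)
  for (counts in ens3@replicateCounts)
    expect_identical(sum(as.integer(names(counts)) * counts), 800L)
  # reproducibility from the root seed
  ensA <- runEnsemble(OneCutModel(0.1), 0.25, 2L, rep(100L, 3), seed = 42)
  ensB <- runEnsemble(OneCutModel(0.1), 0.25, 2L, rep(100L, 3), seed = 42)
  expect_identical(ensA@replicateCounts, ensB@replicateCounts)
})

test_that("short-time simulations keep more long blocks than the theory", {
  # at t = 0.05 the analytic PMF ignores the initial chromosomes and
  # underestimates the probability of ~chromosome-length blocks
  m <- OneCutModel(0.1)
  ens <- runEnsemble(m, tMax = 0.05, replicates = 60L, seed = 23)
  pEmp1000 <- ensembleMean(ens)[1000L]
  pTheory1000 <- blockSizePmf(m, 1000L, 0.05)
  expect_gt(pEmp1000, pTheory1000)
})
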