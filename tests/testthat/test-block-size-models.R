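test_that("one-cut PMF is the conditioned geometric in kappa*t", {
  # kappa*t = ln 2 gives the plain halving geometric
  m <- OneCutModel(log(2))
  expect_equal(blockSizePmf(m, 1L, t = 1), 0.5, tolerance = 1e-12)
  expect_equal(blockSizePmf(m, 2L, t = 1), 0.25, tolerance = 1e-12)
  # direct evaluation at small rate: P(1) = 1 - exp(-0.025)
  expect_equal(blockSizePmf(OneCutModel(0.1), 1L, t = 0.25),
               -expm1(-0.025), tolerance = 1e-12)
  # normalization over n >= 1 up to the analytic geometric tail
  n <- 1:200000
  s <- sum(blockSizePmf(OneCutModel(0.1), n, t = 0.25))
  expect_lt(abs(s + exp(-0.025 * 200000) - 1), 1e-10)
  expect_error(blockSizePmf(OneCutModel(0), 1L, t = 1), "degenerate")
  expect_error(blockSizePmf(OneCutModel(0.1), 1L, t = 0), "degenerate")
  expect_error(blockSizePmf(m, 0L, t = 1), "positive integers")
})

test_that("two-cut span distribution is geometric with the analytic mean", {
  # theta -> infinity collapses the span onto the adjacent region
  expect_equal(twoCutSpanPmf(1L, theta = 500), 1, tolerance = 1e-12)
  # mean by direct summation (oracle) against the closed form
  mBySum <- pmfMeanBySummation(function(n) twoCutSpanPmf(n, theta = 0.5))
  expect_equal(mBySum, 1 / (1 - exp(-0.5)), tolerance = 1e-9)
  expect_equal(meanGeometricSize(0.5), 2.5415, tolerance = 1e-4)
  # the typical fitted span-decay value corresponds to ~2.62 genes
  expect_equal(meanGeometricSize(0.4808), 2.62, tolerance = 2e-3)
  expect_error(twoCutSpanPmf(1L, theta = 0), "degenerate")
})

test_that("two-cut PMF mixes initial- and final-cut geometrics equally", {
  m <- TwoCutModel(gamma = 0.1, theta = 0.5)
  expect_equal(blockSizePmf(m, 1L, t = 0.25), 0.216568, tolerance = 1e-5)
  # direct mixture evaluation at several n
  n <- c(1L, 2L, 5L, 20L, 100L)
  expected <- 0.5 * exp(-0.525 * (n - 1)) * (1 - exp(-0.525)) +
    0.5 * exp(-0.025 * (n - 1)) * (1 - exp(-0.025))
  expect_equal(blockSizePmf(m, n, t = 0.25), expected, tolerance = 1e-12)
  # large theta: first mixture component collapses onto n = 1
  mInf <- TwoCutModel(gamma = 0.1, theta = 200)
  expect_equal(blockSizePmf(mInf, 1L, t = 0.25),
               0.5 + 0.5 * (1 - exp(-0.025)), tolerance = 1e-10)
  expect_equal(sum(blockSizePmf(m, 1:5000, t = 0.25)), 1, tolerance = 1e-10)
  expect_error(blockSizePmf(TwoCutModel(0, 0.5), 1L, t = 1), "degenerate")
})

test_that("combined model reduces to one-cut and two-cut pointwise", {
  n <- 1:200
  t <- 0.25
  expect_equal(
    blockSizePmf(CombinedModel(kappa = 0.3, gamma = 0, theta = 0.5), n, t),
    blockSizePmf(OneCutModel(0.3), n, t), tolerance = 1e-12)
  expect_equal(
    blockSizePmf(CombinedModel(kappa = 0, gamma = 0.1, theta = 0.5), n, t),
    blockSizePmf(TwoCutModel(0.1, 0.5), n, t), tolerance = 1e-12)
  # mixture weights gamma/(kappa+2gamma) and (kappa+gamma)/(kappa+2gamma)
  m <- CombinedModel(0.1, 0.1, 0.5)
  w1 <- 1 / 3; w2 <- 2 / 3
  x <- 0.05  # (kappa + gamma) * t
  expected <- w1 * exp(-(x + 0.5) * (n - 1)) * (1 - exp(-(x + 0.5))) +
    w2 * exp(-x * (n - 1)) * (1 - exp(-x))
  expect_equal(blockSizePmf(m, n, t), expected, tolerance = 1e-12)
  expect_equal(sum(blockSizePmf(m, 1:5000, t)), 1, tolerance = 1e-10)
  expect_error(blockSizePmf(CombinedModel(0, 0, 0.5), 1L, t), "degenerate")
})

test_that("hotspot stationary law and condition vector are exact", {
  m <- HotspotModel(0.5, 0.01, rHC = 0.05, rCH = 0.01)
  expect_equal(unname(hotspotStationary(m)), c(1, 5) / 6, tolerance = 1e-12)
  # symmetric transitions give the uniform stationary law
  expect_equal(unname(hotspotStationary(HotspotModel(1, 1, 0.3, 0.3))),
               c(0.5, 0.5), tolerance = 1e-12)
  # stationarity: pi is a left eigenvector of the transition matrix
  mats <- hotspotMatrices(m, t = 0.25)
  expect_equal(drop(mats$stationary %*% mats$transition),
               mats$stationary, tolerance = 1e-12)
  sig <- hotspotConditionVector(m, t = 0.25)
  expect_equal(sig[["H"]], 0.903957, tolerance = 1e-5)
  expect_equal(sum(sig), 1, tolerance = 1e-12)
  # equal rates: the cut probability cancels, sigma reduces to pi
  mEq <- HotspotModel(0.2, 0.2, 0.05, 0.01)
  expect_equal(hotspotConditionVector(mEq, 0.25)[["H"]],
               hotspotStationary(mEq)[["H"]], tolerance = 1e-12)
  # cold rate zero: every cut is in a hotspot
  expect_equal(
    hotspotConditionVector(HotspotModel(0.5, 0, 0.05, 0.01), 0.25)[["H"]],
    1, tolerance = 1e-12)
  expect_error(hotspotConditionVector(HotspotModel(0, 0, 0.1, 0.1), 1),
               "degenerate")
})

test_that("hotspot matrix PMF agrees with exhaustive spot-sequence
           enumeration", {
  set.seed(401)
  for (rep in 1:10) {
    m <- randomHotspotModel()
    t <- runif(1, 0.1, 0.5)
    for (n in c(1L, 2L, 3L, 5L, 9L)) {
      expect_equal(blockSizePmf(m, n, t), hotspotPmfEnum(m, t, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("hotspot PMF collapses to one-cut at equal rates and is
           label-symmetric", {
  n <- 1:100
  m <- HotspotModel(0.2, 0.2, rHC = 0.7, rCH = 0.05)
  expect_equal(blockSizePmf(m, n, 0.25),
               blockSizePmf(OneCutModel(0.2), n, 0.25), tolerance = 1e-12)
  # constructor canonicalizes swapped labels onto the same chain
  a <- HotspotModel(0.5, 0.01, rHC = 0.05, rCH = 0.01)
  b <- HotspotModel(0.01, 0.5, rHC = 0.01, rCH = 0.05)  # swapped input
  expect_equal(modelParams(a), modelParams(b))
  expect_equal(blockSizePmf(a, n, 0.25), blockSizePmf(b, n, 0.25),
               tolerance = 1e-15)
  # normalization over n >= 1 (geometric tail bounded by the spectral
  # radius of the no-cut propagation matrix)
  lambda <- max(abs(hotspotEigen(a, 0.25)))
  nMax <- ceiling(log(1e-13) / log(lambda))
  expect_equal(sum(blockSizePmf(a, seq_len(nMax), 0.25)), 1,
               tolerance = 1e-10)
})

test_that("2-cut consistency diagnostics have the analytic values and
           monotonicity", {
  m <- TwoCutModel(gamma = 0.1, theta = 0.5)
  expect_equal(overlapError(m, t = 0.25), -expm1(-0.025) * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(overlapError(m, t = 0.25), 0.014975, tolerance = 1e-4)
  # Poisson tail oracle: P(K >= 2) with mean 0.025
  expect_equal(multicutError(m, t = 0.25),
               ppois(1, 0.025, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(multicutError(m, t = 0.25), 3.0734e-4, tolerance = 1e-4)
  expect_equal(overlapError(TwoCutModel(0, 0.5), 1), 0)
  expect_equal(multicutError(TwoCutModel(0, 0.5), 1), 0)
  # monotone in gamma*t, decreasing in theta, bounded in [0, 1)
  gt <- seq(0.01, 5, length.out = 30)
  eO <- vapply(gt, function(g) overlapError(TwoCutModel(g, 0.5), 1),
               numeric(1))
  eM <- vapply(gt, function(g) multicutError(TwoCutModel(g, 0.5), 1),
               numeric(1))
  expect_true(all(diff(eO) > 0) && all(diff(eM) > 0))
  expect_true(all(eO >= 0 & eO < 1) && all(eM >= 0 & eM < 1))
  th <- seq(0.1, 5, length.out = 20)
  eOth <- vapply(th, function(x) overlapError(TwoCutModel(0.5, x), 1),
                 numeric(1))
  expect_true(all(diff(eOth) < 0))
  # gamma -> infinity limit: overlap error approaches exp(-theta)
  expect_equal(overlapError(TwoCutModel(1e6, 0.5), 1), exp(-0.5),
               tolerance = 1e-9)
})

test_that("truncated PMFs renormalize exactly on the fitting window", {
  # single-size window concentrates all mass
  tp <- truncatedPmf(TwoCutModel(0.1, 0.5), 0.25, 7, 7)
  expect_equal(tp@prob, 1)
  # memorylessness: truncating a geometric leaves the same ratio
  tp1 <- truncatedPmf(OneCutModel(0.2), 0.5, 3, 60)
  ratios <- tp1@prob[-1] / tp1@prob[-length(tp1@prob)]
  expect_equal(ratios, rep(exp(-0.1), length(ratios)), tolerance = 1e-12)
  # hotspot window used in fitting sums to one to near machine precision
  tph <- truncatedPmf(HotspotModel(0.5, 0.01, 0.05, 0.01), 0.25, 3, 1000)
  expect_equal(sum(tph@prob), 1, tolerance = 1e-12)
  expect_true(all(tph@prob >= 0))
  expect_error(truncatedPmf(OneCutModel(0.1), 0.25, 5, 3), "nMin <= nMax")
})
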