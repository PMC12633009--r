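# Independent oracles and generators shared across the test files.

# Exhaustive-enumeration oracle for the hotspot block size PMF: sums over
# every hot/cold state sequence (s1, ..., s_{n+1}) the chain weight times
# the no-cut probabilities of the n-1 interior regions and the cut
# probability of the terminal region. Exponential in n; usable for n <= ~14.
hotspotPmfEnum <- function(model, t, n) {
  mats <- hotspotMatrices(model, t)
  Tm <- mats$transition; U <- mats$noCut; C <- mats$cut
  sig <- mats$condition
  states <- as.matrix(expand.grid(rep(list(1:2), n + 1L)))
  p <- sig[states[, 1L]]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      idx <- cbind(states[, i], states[, i + 1L])
      p <- p * Tm[idx] * U[idx]
    }
  }
  idx <- cbind(states[, n], states[, n + 1L])
  sum(p * Tm[idx] * C[idx])
}

# random hotspot parameter draw covering several magnitudes
randomHotspotModel <- function() {
  HotspotModel(kappaH = 10^runif(1, -1.5, 0.7),
               kappaC = 10^runif(1, -2.5, 0.3),
               rHC = runif(1, 0.01, 1),
               rCH = runif(1, 0.01, 1))
}

# mixture eigenvalues of the no-cut propagation matrix T (*) U; these (with
# the conditioned cut distribution) are the identifiable reparameterization
# of the hotspot model
hotspotEigen <- function(model, t) {
  mats <- hotspotMatrices(model, t)
  sort(eigen(mats$transition * mats$noCut, only.values = TRUE)$values,
       decreasing = TRUE)
}

# directly-summed mean of a PMF given as a function of n (summation oracle)
pmfMeanBySummation <- function(pmfFun, nMax = 20000L) {
  n <- seq_len(nMax)
  sum(n * pmfFun(n))
}
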