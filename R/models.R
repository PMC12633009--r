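#' @include AllGenerics.R
NULL

# log(1 - exp(-x)) for x > 0, stable for both tiny and large x
.log1mexp <- function(x) {
  ifelse(x > log(2), log1p(-exp(-x)), log(-expm1(-x)))
}

# elementwise log(exp(a) + exp(b)) without overflow; -Inf handled
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log pmf of the unit-shifted geometric with exponential parameter x > 0:
# p(n) = exp(-x (n-1)) (1 - exp(-x)), n = 1, 2, ...
.logGeom <- function(n, x) -x * (n - 1) + .log1mexp(x)

.checkN <- function(n) {
  if (any(n < 1) || any(n != floor(n)))
    stop("block sizes n must be positive integers")
}

.degenerate <- function(what) {
  stop("degenerate model: ", what, call. = FALSE)
}

#' @rdname blockSizePmf
setMethod("blockSizePmf", "OneCutModel", function(model, n, t, log = FALSE) {
  .checkN(n)
  kt <- model@kappa * t
  if (kt <= 0) .degenerate("kappa * t must be > 0 (no cuts ever occur)")
  lp <- .logGeom(n, kt)
  if (log) lp else exp(lp)
})

#' @rdname blockSizePmf
setMethod("blockSizePmf", "TwoCutModel", function(model, n, t, log = FALSE) {
  .checkN(n)
  gt <- model@gamma * t
  if (gt <= 0) .degenerate("gamma * t must be > 0")
  # equal-weight mixture: conditioning on an initial vs a final 2-cut
  lp <- .logaddexp(base::log(0.5) + .logGeom(n, gt + model@theta),
                   base::log(0.5) + .logGeom(n, gt))
  if (log) lp else exp(lp)
})

#' @rdname blockSizePmf
setMethod("blockSizePmf", "CombinedModel", function(model, n, t, log = FALSE) {
  .checkN(n)
  k <- model@kappa; g <- model@gamma
  if (k + 2 * g <= 0) .degenerate("kappa + 2 gamma must be > 0")
  if ((k + g) * t <= 0) .degenerate("(kappa + gamma) * t must be > 0")
  w1 <- g / (k + 2 * g)        # conditioning on an initial 2-cut
  w2 <- (k + g) / (k + 2 * g)  # conditioning on a 1-cut or final 2-cut
  x2 <- (k + g) * t
  t1 <- if (w1 > 0) base::log(w1) + .logGeom(n, x2 + model@theta) else
    rep(-Inf, length(n))
  lp <- .logaddexp(t1, base::log(w2) + .logGeom(n, x2))
  if (log) lp else exp(lp)
})

#' @rdname blockSizePmf
setMethod("blockSizePmf", "HotspotModel", function(model, n, t, log = FALSE) {
  .checkN(n)
  nMax <- max(n)
  lp <- .hotspotLogPmfVector(model, t, nMax)[n]
  if (log) lp else exp(lp)
})

# full log-PMF vector for n = 1..nMax via successive row-vector products
.hotspotLogPmfVector <- function(model, t, nMax) {
  .lpHotspotVec(model@kappaH, model@kappaC, model@rHC, model@rCH, t, nMax)
}

# slot-free hotspot log-PMF kernel shared with the fitting objective
.lpHotspotVec <- function(kH, kC, rHC, rCH, t, nMax) {
  if (kH * t <= 0 && kC * t <= 0)
    .degenerate("at least one of kappaH * t, kappaC * t must be > 0")
  piH <- rCH / (rHC + rCH)
  piC <- 1 - piH
  uH <- exp(-kH * t); uC <- exp(-kC * t)
  wH <- (1 - uH) * piH; wC <- (1 - uC) * piC
  sigma <- c(wH, wC) / (wH + wC)
  M <- matrix(c((1 - rHC) * uH, rCH * uH,
                rHC * uC, (1 - rCH) * uC), nrow = 2)  # T (*) U, column-major
  cutRowSums <- c((1 - rHC) * (1 - uH) + rHC * (1 - uC),
                  rCH * (1 - uH) + (1 - rCH) * (1 - uC))
  hotspot_log_pmf_cpp(sigma, M, cutRowSums, as.integer(nMax))
}

# log-PMF of model `id` with parameter vector `par` on the window
# nMin..nMax, without S4 construction; used by the fitting objective
.logPmfWindow <- function(id, par, t, nMin, nMax) {
  n <- nMin:nMax
  switch(id,
    one_cut = .logGeom(n, par[1L] * t),
    two_cut = .logaddexp(
      base::log(0.5) + .logGeom(n, par[1L] * t + par[2L]),
      base::log(0.5) + .logGeom(n, par[1L] * t)),
    combined = {
      k <- par[1L]; g <- par[2L]
      w1 <- g / (k + 2 * g)
      t1 <- if (w1 > 0) base::log(w1) + .logGeom(n, (k + g) * t + par[3L])
        else rep(-Inf, length(n))
      .logaddexp(t1, base::log((k + g) / (k + 2 * g)) +
                   .logGeom(n, (k + g) * t))
    },
    hotspot = .lpHotspotVec(par[1L], par[2L], par[3L], par[4L], t, nMax)[n],
    stop("unknown model id: ", id))
}

#' Span distribution of a correlated breakpoint pair
#'
#' Probability that the final cut of a 2-cut lands `n` genes away from its
#' initial cut: a unit-shifted geometric with per-region continuation
#' probability `exp(-theta)`, i.e. `p(n) = exp(-theta (n-1)) (1 - exp(-theta))`.
#' Its mean span is `1 / (1 - exp(-theta))` genes (see
#' [meanGeometricSize()]).
#'
#' @param n Positive integer spans (genes), vectorized.
#' @param theta Positive span-decay parameter.
#' @param log Return log probabilities.
#' @return Numeric vector of (log) probabilities.
#' @examples
#' twoCutSpanPmf(1:5, theta = 0.5)
#' @export
twoCutSpanPmf <- function(n, theta, log = FALSE) {
  .checkN(n)
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0)
    .degenerate("theta must be > 0 for the 2-cut span distribution")
  lp <- .logGeom(n, theta)
  if (log) lp else exp(lp)
}

#' Hotspot model machinery
#'
#' The fragile-breakage (hotspot) model places hot/cold labels on inter-gene
#' regions by a two-state Markov chain. `hotspotStationary()` returns the
#' stationary probabilities `(piH, piC) = (rCH, rHC) / (rCH + rHC)`.
#' `hotspotConditionVector()` returns the probability that a conditioned-on
#' cut sits in a hotspot versus a coldspot,
#' `sigmaH = (1 - exp(-kappaH t)) piH / [(1 - exp(-kappaH t)) piH +
#' (1 - exp(-kappaC t)) piC]`, using the exact exponential form (the
#' rate-ratio form sometimes quoted is its small-rate approximation).
#' `hotspotMatrices()` assembles the 2x2 transition matrix `T`, the no-cut
#' matrix `U` (columns `exp(-kappaH t)`, `exp(-kappaC t)`), the cut matrix
#' `C = 1 - U`, the condition row vector and the stationary distribution.
#'
#' @param model A [HotspotModel].
#' @param t Evolutionary distance (subs/site).
#' @return `hotspotStationary()` and `hotspotConditionVector()` return named
#'   length-2 numeric vectors `(H, C)`; `hotspotMatrices()` a list with
#'   elements `transition`, `noCut`, `cut`, `condition`, `stationary`.
#' @examples
#' m <- HotspotModel(0.5, 0.01, rHC = 0.05, rCH = 0.01)
#' hotspotStationary(m)
#' hotspotConditionVector(m, t = 0.25)
#' @name hotspotMachinery
NULL

#' @rdname hotspotMachinery
setMethod("hotspotStationary", "HotspotModel", function(model) {
  s <- model@rHC + model@rCH
  if (s <= 0) stop("no unique stationary distribution when rHC = rCH = 0")
  c(H = model@rCH / s, C = model@rHC / s)
})

#' @rdname hotspotMachinery
setMethod("hotspotConditionVector", "HotspotModel", function(model, t) {
  if (model@kappaH * t <= 0 && model@kappaC * t <= 0)
    .degenerate("at least one of kappaH * t, kappaC * t must be > 0")
  pi <- hotspotStationary(model)
  wH <- -expm1(-model@kappaH * t) * pi[["H"]]
  wC <- -expm1(-model@kappaC * t) * pi[["C"]]
  c(H = wH / (wH + wC), C = wC / (wH + wC))
})

#' @rdname hotspotMachinery
setMethod("hotspotMatrices", "HotspotModel", function(model, t) {
  T <- matrix(c(1 - model@rHC, model@rHC,
                model@rCH, 1 - model@rCH), nrow = 2, byrow = TRUE,
              dimnames = list(c("H", "C"), c("H", "C")))
  u <- c(H = exp(-model@kappaH * t), C = exp(-model@kappaC * t))
  U <- rbind(H = u, C = u)
  list(transition = T, noCut = U, cut = 1 - U,
       condition = hotspotConditionVector(model, t),
       stationary = hotspotStationary(model))
})

#' Internal-consistency diagnostics of the correlated breakage model
#'
#' The closed-form 2-cut distribution neglects (i) 2-cut pairs whose span
#' straddles the reference cut ("overlapping" 2-cuts) and (ii) two or more
#' initial 2-cuts at the same inter-gene region. `overlapError()` returns
#' the probability of the first neglected event,
#' `epsO = (1 - exp(-gamma t)) exp(-theta)`, and `multicutError()` the
#' second, `epsM = 1 - exp(-gamma t) - gamma t exp(-gamma t)` (the Poisson
#' tail `P(K >= 2)` with mean `gamma t`). Both lie in `[0, 1)`; small values
#' mean the fitted model is internally consistent.
#'
#' @param model A [TwoCutModel] or [CombinedModel].
#' @param t Evolutionary distance (subs/site).
#' @return A probability.
#' @examples
#' overlapError(TwoCutModel(0.1, 0.5), t = 0.25)
#' multicutError(TwoCutModel(0.1, 0.5), t = 0.25)
#' @name consistencyDiagnostics
NULL

.overlapError <- function(gamma, theta, t) -expm1(-gamma * t) * exp(-theta)
.multicutError <- function(gamma, t) {
  gt <- gamma * t
  -expm1(-gt) - gt * exp(-gt)
}

#' @rdname consistencyDiagnostics
setMethod("overlapError", "TwoCutModel", function(model, t)
  .overlapError(model@gamma, model@theta, t))

#' @rdname consistencyDiagnostics
setMethod("overlapError", "CombinedModel", function(model, t)
  .overlapError(model@gamma, model@theta, t))

#' @rdname consistencyDiagnostics
setMethod("multicutError", "TwoCutModel", function(model, t)
  .multicutError(model@gamma, t))

#' @rdname consistencyDiagnostics
setMethod("multicutError", "CombinedModel", function(model, t)
  .multicutError(model@gamma, t))

#' Truncated and renormalized model PMF
#'
#' Evaluates a model's block size PMF on `[nMin, nMax]` and renormalizes it
#' to sum to one, the convention under which models are fitted to empirical
#' distributions (both are normalized over the same window). The
#' renormalization is done in log space so that steep distributions keep
#' accurate tail probabilities.
#'
#' @param model A [BreakageModel].
#' @param t Evolutionary distance (subs/site).
#' @param nMin,nMax Integer truncation bounds, `1 <= nMin <= nMax`.
#' @return A [BlockSizePMF].
#' @examples
#' truncatedPmf(OneCutModel(0.1), t = 0.25, nMin = 3, nMax = 50)
#' @name truncatedPmf
NULL

#' @rdname truncatedPmf
setMethod("truncatedPmf", "BreakageModel", function(model, t, nMin, nMax) {
  nMin <- as.integer(nMin); nMax <- as.integer(nMax)
  if (nMin < 1L || nMax < nMin) stop("need 1 <= nMin <= nMax")
  n <- nMin:nMax
  lp <- blockSizePmf(model, n, t, log = TRUE)
  m <- max(lp)
  logZ <- m + base::log(sum(exp(lp - m)))
  lp <- lp - logZ
  p <- exp(lp)
  new("BlockSizePMF", support = n, prob = p / sum(p), logProb = lp)
})

#' @rdname modelId
setMethod("modelId", "OneCutModel", function(object) "one_cut")
#' @rdname modelId
setMethod("modelId", "TwoCutModel", function(object) "two_cut")
#' @rdname modelId
setMethod("modelId", "CombinedModel", function(object) "combined")
#' @rdname modelId
setMethod("modelId", "HotspotModel", function(object) "hotspot")

#' Model identity, parameter count and parameter vector
#'
#' `modelId()` maps a model object to its string identifier (`"one_cut"`,
#' `"two_cut"`, `"combined"`, `"hotspot"`); `nParams()` gives the number of
#' free parameters (1, 2, 3, 4 respectively); `modelParams()` returns the
#' named parameter vector.
#'
#' @param object A [BreakageModel] (or, for `modelId`, a [FitResult]).
#' @return A string, an integer, or a named numeric vector.
#' @name modelId
NULL

#' @rdname modelId
setMethod("nParams", "OneCutModel", function(object) 1L)
#' @rdname modelId
setMethod("nParams", "TwoCutModel", function(object) 2L)
#' @rdname modelId
setMethod("nParams", "CombinedModel", function(object) 3L)
#' @rdname modelId
setMethod("nParams", "HotspotModel", function(object) 4L)

#' @rdname modelId
setMethod("modelParams", "OneCutModel", function(object)
  c(kappa = object@kappa))
#' @rdname modelId
setMethod("modelParams", "TwoCutModel", function(object)
  c(gamma = object@gamma, theta = object@theta))
#' @rdname modelId
setMethod("modelParams", "CombinedModel", function(object)
  c(kappa = object@kappa, gamma = object@gamma, theta = object@theta))
#' @rdname modelId
setMethod("modelParams", "HotspotModel", function(object)
  c(kappaH = object@kappaH, kappaC = object@kappaC,
    rHC = object@rHC, rCH = object@rCH))

setMethod("show", "BreakageModel", function(object) {
  p <- modelParams(object)
  cat(sprintf("%s breakage model (%d parameter%s)\n", modelId(object),
              nParams(object), if (nParams(object) > 1L) "s" else ""))
  cat(" ", paste(sprintf("%s = %g", names(p), p), collapse = ", "), "\n")
})

setMethod("show", "BlockSizePMF", function(object) {
  cat(sprintf("BlockSizePMF on [%d, %d] (%d sizes)\n",
              min(object@support), max(object@support),
              length(object@support)))
})

#' Construct a model from an id and a parameter vector
#'
#' Inverse of [modelParams()]: builds the model object named by `id` from a
#' parameter vector in the canonical order (`kappa`; `gamma, theta`;
#' `kappa, gamma, theta`; `kappaH, kappaC, rHC, rCH`).
#'
#' @param id Model identifier string.
#' @param par Numeric parameter vector of the matching length.
#' @return A [BreakageModel].
#' @export
makeModel <- function(id, par) {
  switch(id,
    one_cut = OneCutModel(par[[1L]]),
    two_cut = TwoCutModel(par[[1L]], par[[2L]]),
    combined = CombinedModel(par[[1L]], par[[2L]], par[[3L]]),
    hotspot = HotspotModel(par[[1L]], par[[2L]], par[[3L]], par[[4L]]),
    stop("unknown model id: ", id))
}

#' Names of the four breakage models
#'
#' @return Character vector of model ids ordered by parameter count.
#' @export
modelIds <- function() c("one_cut", "two_cut", "combined", "hotspot")
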