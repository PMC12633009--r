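#' @include models.R
NULL

#' Empirical block size distribution
#'
#' Builds an [EmpiricalPMF] from observed synteny block sizes for one genome
#' pair. Sizes below `nMin` are dropped (short blocks are unreliable calls
#' upstream; the default `nMin = 3` matches the minimum block size used in
#' microsynteny inference) and probabilities are renormalized over
#' `[nMin, nMax]` where `nMax` is the largest observed size.
#'
#' @param x Block sizes as (i) an integer vector of individual block sizes,
#'   (ii) a named numeric vector of counts with sizes as names, or (iii) a
#'   two-column data frame `(block_size, count)`.
#' @param t Evolutionary distance between the two genomes (mean amino-acid
#'   substitutions per site summed over both lineages).
#' @param nMin Smallest block size retained (default 3).
#' @param pairId Identifier for the genome pair.
#' @return An [EmpiricalPMF].
#' @examples
#' empiricalPmf(c(3, 3, 5, 5), t = 0.2)
#' @export
empiricalPmf <- function(x, t, nMin = 3L, pairId = "pair") {
  nMin <- as.integer(nMin)
  if (is.data.frame(x)) {
    sizes <- as.integer(x[[1L]])
    counts <- as.numeric(x[[2L]])
  } else if (!is.null(names(x))) {
    sizes <- as.integer(names(x))
    counts <- as.numeric(x)
  } else {
    tab <- table(as.integer(x))
    sizes <- as.integer(names(tab))
    counts <- as.numeric(tab)
  }
  if (any(is.na(sizes)) || any(sizes < 1L)) stop("block sizes must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  agg <- tapply(counts, sizes, sum)
  sizes <- as.integer(names(agg))
  counts <- as.numeric(agg)
  keep <- sizes >= nMin & counts > 0
  if (!any(keep))
    stop("no blocks of size >= nMin = ", nMin, " observed")
  sizes <- sizes[keep]; counts <- counts[keep]
  ord <- order(sizes)
  sizes <- sizes[ord]; counts <- counts[ord]
  new("EmpiricalPMF", pairId = as.character(pairId), t = as.numeric(t),
      sizes = sizes, counts = counts, prob = counts / sum(counts),
      nMin = nMin, nMax = max(sizes))
}

setMethod("show", "EmpiricalPMF", function(object) {
  cat(sprintf(
    "EmpiricalPMF '%s': %d block sizes on [%d, %d], %g blocks, t = %g\n",
    object@pairId, length(object@sizes), object@nMin, object@nMax,
    sum(object@counts), object@t))
})

#' @rdname empiricalPmf
#' @param object An [EmpiricalPMF].
#' @export
pairId <- function(object) object@pairId

#' @rdname empiricalPmf
#' @export
evolDistance <- function(object) object@t

#' @rdname empiricalPmf
#' @export
blockCounts <- function(object) {
  counts <- object@counts
  names(counts) <- object@sizes
  counts
}

#' Kullback-Leibler divergence between empirical and model distributions
#'
#' `D_KL(Phat || P) = sum_n Phat(n) log(Phat(n) / P(n))` in nats, summed over
#' `[nMin, nMax]` with the convention `0 log 0 = 0` (block sizes with zero
#' observed count contribute nothing). Both distributions must be normalized
#' over the same window; `model` is a [BlockSizePMF] from [truncatedPmf()]
#' whose support must equal the empirical `[nMin, nMax]`. If the model
#' assigns zero probability to an observed size the divergence is `+Inf`
#' (returned, not raised).
#'
#' @param empirical An [EmpiricalPMF].
#' @param model A [BlockSizePMF] on the same support window.
#' @return Non-negative number (possibly `Inf`).
#' @examples
#' e <- empiricalPmf(c(3, 3, 4, 4), t = 0.2)
#' klDivergence(e, truncatedPmf(OneCutModel(0.5), 0.2, 3, 4))
#' @export
klDivergence <- function(empirical, model) {
  stopifnot(is(empirical, "EmpiricalPMF"), is(model, "BlockSizePMF"))
  if (min(model@support) != empirical@nMin ||
      max(model@support) != empirical@nMax)
    stop("model PMF support must equal the empirical [nMin, nMax] window")
  lp <- model@logProb[empirical@sizes - empirical@nMin + 1L]
  if (any(is.infinite(lp))) return(Inf)
  sum(empirical@prob * (base::log(empirical@prob) - lp))
}

# per-model box constraints: rates in [1e-8, 1e2], probabilities in [1e-8, 1]
.fitBounds <- function(id, rateLower = 1e-8, rateUpper = 1e2) {
  r <- c(rateLower, rateUpper)
  p <- c(rateLower, 1)
  switch(id,
    one_cut = list(lower = r[1L], upper = r[2L], names = "kappa"),
    two_cut = list(lower = rep(r[1L], 2L), upper = rep(r[2L], 2L),
                   names = c("gamma", "theta")),
    combined = list(lower = rep(r[1L], 3L), upper = rep(r[2L], 3L),
                    names = c("kappa", "gamma", "theta")),
    hotspot = list(lower = c(r[1L], r[1L], p[1L], p[1L]),
                   upper = c(r[2L], r[2L], 1, 1),
                   names = c("kappaH", "kappaC", "rHC", "rCH")),
    stop("unknown model id: ", id))
}

#' Fit a breakage model to an empirical block size distribution
#'
#' Minimizes the Kullback-Leibler divergence between the empirical
#' distribution and the model's truncated PMF over the parameter box
#' (rates in `[1e-8, 100]` sites/sub, transition probabilities in
#' `[1e-8, 1]`), using multi-start bounded quasi-Newton optimization
#' (`optim(method = "L-BFGS-B")` with numerically estimated gradients).
#' Starting points are drawn independently and uniformly on the linear scale
#' of each interval (`startScale = "log"` switches to log-uniform draws);
#' the restart achieving the lowest divergence wins, ties broken by lowest
#' start index. Hotspot fits are canonicalized to `kappaH >= kappaC`.
#'
#' Internally each local solve runs on log-transformed parameters (with
#' correspondingly transformed bounds), which makes the finite-difference
#' gradient scale-free across parameter magnitudes spanning
#' `1e-8` to `1e2`; the starting points themselves are still the
#' linear-uniform draws.
#'
#' Only the products rate x `t` enter any PMF, so rates are identified only
#' because `t` is supplied per pair; fitted rates are reported in sites/sub.
#'
#' @param empirical An [EmpiricalPMF].
#' @param model Model id (`"one_cut"`, `"two_cut"`, `"combined"`,
#'   `"hotspot"`) or a [BreakageModel] prototype.
#' @param restarts Number of random starting points (default 50).
#' @param seed Optional integer seed for the starting points.
#' @param startScale `"linear"` (default) or `"log"` uniform starts.
#' @param extraStarts Optional list of additional deterministic starting
#'   parameter vectors (appended after the random starts; used by
#'   [fitAllModels()] to warm-start each model from the embedded optimum of
#'   the model with one fewer parameter).
#' @param control Passed to [stats::optim()]; defaults to
#'   `list(factr = 1e5, maxit = 500)` (near machine-precision objective tolerance).
#' @return A [FitResult].
#' @examples
#' e <- empiricalPmf(rgeom(500, prob = 0.1) + 1L, t = 0.25)
#' fitModel(e, "one_cut", restarts = 10, seed = 1)
#' @export
fitModel <- function(empirical, model, restarts = 50L, seed = NULL,
                     startScale = c("linear", "log"), extraStarts = list(),
                     control = list(factr = 10, maxit = 1000L)) {
  stopifnot(is(empirical, "EmpiricalPMF"))
  id <- if (is(model, "BreakageModel")) modelId(model) else
    match.arg(model, modelIds())
  startScale <- match.arg(startScale)
  if (empirical@t <= 0)
    stop("fitting requires evolutionary distance t > 0")
  if (restarts < 1L) stop("restarts must be >= 1")
  b <- .fitBounds(id)
  p <- length(b$names)
  if (!is.null(seed)) set.seed(seed)
  starts <- matrix(stats::runif(restarts * p), nrow = restarts)
  starts <- if (startScale == "linear") {
    sweep(sweep(starts, 2L, b$upper - b$lower, "*"), 2L, b$lower, "+")
  } else {
    exp(sweep(sweep(starts, 2L, base::log(b$upper) - base::log(b$lower), "*"),
              2L, base::log(b$lower), "+"))
  }
  if (length(extraStarts))
    starts <- rbind(starts, do.call(rbind, lapply(extraStarts, unname)))
  phat <- empirical@prob
  logPhat <- base::log(phat)
  sizeIdx <- empirical@sizes - empirical@nMin + 1L
  objective <- function(logPar) {
    lp <- tryCatch(
      .logPmfWindow(id, exp(logPar), empirical@t, empirical@nMin,
                    empirical@nMax),
      error = function(e) NULL)
    if (is.null(lp)) return(1e10)
    m <- max(lp)
    lp <- lp - (m + base::log(sum(exp(lp - m))))
    kl <- sum(phat * (logPhat - lp[sizeIdx]))
    if (!is.finite(kl)) 1e10 else kl
  }
  best <- NULL
  bestIdx <- NA_integer_
  converged <- 0L
  failures <- character()
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(base::log(starts[i, ]), objective, method = "L-BFGS-B",
                   lower = base::log(b$lower), upper = base::log(b$upper),
                   control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    res$par <- exp(res$par)
    if (res$convergence == 0L) converged <- converged + 1L
    if (is.null(best) || res$value < best$value) {
      best <- res
      bestIdx <- i
    }
  }
  if (is.null(best))
    stop("all ", restarts, " restarts failed; messages: ",
         paste(unique(failures), collapse = "; "))
  fitted <- makeModel(id, best$par)  # hotspot canonicalization happens here
  new("FitResult", modelId = id, model = fitted,
      kl = max(best$value, 0), t = empirical@t, nMin = empirical@nMin,
      nMax = empirical@nMax, restartsConverged = converged,
      bestStartIndex = bestIdx)
}

# Construct hotspot parameter vectors whose block size PMF approximates a
# two-geometric mixture w1 * geom(x1) + (1 - w1) * geom(x2), x1 >= x2 (the
# form every lower-parameter model takes). With kappaC ~ 0 the no-cut
# propagation matrix has trace (1-rHC) uH + (1-rCH) and determinant
# uH (1 - rHC - rCH); matching its eigenvalues to (e^{-x2}, e^{-x1}) fixes
# (uH, rHC) for each rCH, leaving a one-parameter family scanned to vary
# the mixture weight. Used as deterministic warm starts for the nested
# fitting chain; candidates violating the box are dropped.
.hotspotMixtureStarts <- function(x1, x2, t) {
  L1 <- exp(-x2)  # dominant eigenvalue
  L2 <- exp(-x1)
  out <- list()
  for (rCH in 10^seq(-4, 0, length.out = 17L)) {
    a <- L1 + L2 - (1 - rCH)          # (1 - rHC) uH
    uH <- (a - L1 * L2) / rCH
    if (!is.finite(uH) || uH <= 0 || uH >= 1) next
    rHC <- 1 - a / uH
    if (!is.finite(rHC) || rHC < 1e-8 || rHC > 1) next
    kH <- -base::log(uH) / t
    if (kH < 1e-8 || kH > 100) next
    out <- c(out, list(c(kappaH = kH, kappaC = 1e-8,
                         rHC = rHC, rCH = rCH)))
  }
  out
}

# deterministic warm starts for model `id` embedding the optima of the
# already-fitted lower-parameter models
.nestedWarmStarts <- function(id, fits, t) {
  ws <- list()
  pk <- function(f) modelParams(f@model)
  if (id == "two_cut" && !is.null(fits$one_cut)) {
    # theta at the upper bound removes the paired component from the
    # truncated window, leaving the plain geometric
    ws <- c(ws, list(c(gamma = pk(fits$one_cut)[["kappa"]], theta = 100)))
  }
  if (id == "combined") {
    if (!is.null(fits$two_cut)) {
      p <- pk(fits$two_cut)
      ws <- c(ws, list(c(kappa = 1e-8, gamma = p[["gamma"]],
                         theta = p[["theta"]])))
    }
    if (!is.null(fits$one_cut))
      ws <- c(ws, list(c(kappa = pk(fits$one_cut)[["kappa"]],
                         gamma = 1e-8, theta = 100)))
  }
  if (id == "hotspot") {
    if (!is.null(fits$one_cut)) {
      k <- pk(fits$one_cut)[["kappa"]]
      ws <- c(ws, list(c(kappaH = k, kappaC = k, rHC = 0.5, rCH = 0.5)))
    }
    mix <- NULL
    if (!is.null(fits$combined)) {
      p <- pk(fits$combined)
      mix <- c((p[["kappa"]] + p[["gamma"]]) * t + p[["theta"]],
               (p[["kappa"]] + p[["gamma"]]) * t)
    } else if (!is.null(fits$two_cut)) {
      p <- pk(fits$two_cut)
      mix <- c(p[["gamma"]] * t + p[["theta"]], p[["gamma"]] * t)
    }
    if (!is.null(mix))
      ws <- c(ws, .hotspotMixtureStarts(mix[1L], mix[2L], t))
  }
  ws
}

#' Fit all four models to one empirical distribution
#'
#' Applies [fitModel()] for each model in order of parameter count
#' (`one_cut`, `two_cut`, `combined`, `hotspot`). Because the models are
#' nested, each fit must reach a divergence at least as low as the model
#' with one fewer parameter; to make that guarantee hold numerically and
#' not just in principle, each model's solve receives — in addition to its
#' random restarts — deterministic warm starts that embed the optimum of
#' the previously fitted lower-parameter models into its own parameter
#' space (monotone descent from an embedded optimum can only improve it).
#' Set `warmStart = FALSE` for fully independent per-model fits.
#'
#' @inheritParams fitModel
#' @param models Model ids to fit (default all four).
#' @param warmStart Chain the fits through embedded-optimum starting points
#'   (default `TRUE`).
#' @return Named list of [FitResult], in the order given.
#' @export
fitAllModels <- function(empirical, models = modelIds(), restarts = 50L,
                         seed = NULL, startScale = c("linear", "log"),
                         warmStart = TRUE,
                         control = list(factr = 10, maxit = 1000L)) {
  startScale <- match.arg(startScale)
  if (!is.null(seed)) set.seed(seed)
  fitSeeds <- sample.int(.Machine$integer.max - 1L, length(models))
  fits <- list()
  for (i in seq_along(models)) {
    extra <- if (warmStart)
      .nestedWarmStarts(models[i], fits, empirical@t) else list()
    fits[[models[i]]] <-
      fitModel(empirical, models[i], restarts = restarts,
               seed = fitSeeds[i], startScale = startScale,
               extraStarts = extra, control = control)
  }
  fits
}

setMethod("show", "FitResult", function(object) {
  p <- modelParams(object@model)
  cat(sprintf("FitResult: %s model, D_KL = %.6g nats\n", object@modelId,
              object@kl))
  cat(" ", paste(sprintf("%s = %.6g", names(p), p), collapse = ", "), "\n")
  cat(sprintf("  fitted on [%d, %d] at t = %g; %d restarts converged\n",
              object@nMin, object@nMax, object@t,
              object@restartsConverged))
})

#' @rdname modelId
setMethod("modelId", "FitResult", function(object) object@modelId)

#' @rdname fitModel
#' @param fit A [FitResult].
#' @export
klDiv <- function(fit) fit@kl

#' @rdname fitModel
#' @export
fittedModel <- function(fit) fit@model

#' Tabulate a set of fit results
#'
#' Flattens a list of [FitResult] objects (e.g. from [fitAllModels()]) into
#' a data frame with one row per model: identifier, parameter estimates,
#' divergence, and the 2-cut consistency diagnostics where applicable.
#'
#' @param fits List of [FitResult] objects.
#' @param pairId Optional pair identifier column value.
#' @return A `data.frame`.
#' @export
fitSummary <- function(fits, pairId = NA_character_) {
  do.call(rbind, lapply(fits, function(f) {
    p <- modelParams(f@model)
    data.frame(
      pair_id = pairId, model = f@modelId, n_params = nParams(f@model),
      kl = f@kl,
      kappa = if ("kappa" %in% names(p)) p[["kappa"]] else NA_real_,
      gamma = if ("gamma" %in% names(p)) p[["gamma"]] else NA_real_,
      theta = if ("theta" %in% names(p)) p[["theta"]] else NA_real_,
      kappaH = if ("kappaH" %in% names(p)) p[["kappaH"]] else NA_real_,
      kappaC = if ("kappaC" %in% names(p)) p[["kappaC"]] else NA_real_,
      rHC = if ("rHC" %in% names(p)) p[["rHC"]] else NA_real_,
      rCH = if ("rCH" %in% names(p)) p[["rCH"]] else NA_real_,
      eps_overlap = if (f@modelId %in% c("two_cut", "combined"))
        overlapError(f@model, f@t) else NA_real_,
      eps_multicut = if (f@modelId %in% c("two_cut", "combined"))
        multicutError(f@model, f@t) else NA_real_,
      row.names = NULL)
  }))
}
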