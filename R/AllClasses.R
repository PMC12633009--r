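#' @import methods
NULL

#' Breakage model parameter classes
#'
#' S4 containers for the parameters of the four synteny-decay models.
#' All rates are in units of sites/(substitution x inter-gene region), so a
#' rate multiplied by an evolutionary distance `t` (mean amino-acid
#' substitutions per site summed over both lineages) gives the expected
#' number of cut events per inter-gene region.
#'
#' * `OneCutModel(kappa)` — random breakage: single breakpoints ("1-cuts")
#'   fall uniformly and independently across inter-gene regions at rate
#'   `kappa`.
#' * `TwoCutModel(gamma, theta)` — correlated breakage: breakpoint pairs
#'   ("2-cuts") mimicking inversions; an initial cut occurs at rate `gamma`
#'   and its partner lands a geometrically distributed span away, with
#'   per-region continuation probability `exp(-theta)`.
#' * `CombinedModel(kappa, gamma, theta)` — both cut types at once.
#' * `HotspotModel(kappaH, kappaC, rHC, rCH)` — fragile breakage: 1-cuts at
#'   rate `kappaH` in hotspots and `kappaC` in coldspots, with hot/cold
#'   labels arranged along the chromosome by a two-state Markov chain with
#'   transition probabilities `rHC` (hot to cold) and `rCH` (cold to hot).
#'
#' `HotspotModel` is canonicalized on construction: the model is invariant
#' under swapping the two state labels together with their transition
#' probabilities, so the labels are always chosen such that
#' `kappaH >= kappaC`.
#'
#' @param kappa,gamma,theta,kappaH,kappaC,rHC,rCH Non-negative numeric
#'   scalars; `rHC` and `rCH` must lie in (0, 1].
#' @return An object of the corresponding model class, all of which extend
#'   the virtual class `BreakageModel`.
#' @examples
#' OneCutModel(0.1)
#' HotspotModel(kappaH = 0.5, kappaC = 0.01, rHC = 0.05, rCH = 0.01)
#' @aliases BreakageModel-class OneCutModel-class TwoCutModel-class
#'   CombinedModel-class HotspotModel-class
#' @name BreakageModel
NULL

setClass("BreakageModel", representation("VIRTUAL"))

.checkRate <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    return(sprintf("%s must be a single finite non-negative number", what))
  NULL
}

setClass("OneCutModel", contains = "BreakageModel",
  representation(kappa = "numeric"),
  validity = function(object) {
    msg <- .checkRate(object@kappa, "kappa")
    if (is.null(msg)) TRUE else msg
  })

setClass("TwoCutModel", contains = "BreakageModel",
  representation(gamma = "numeric", theta = "numeric"),
  validity = function(object) {
    msg <- c(.checkRate(object@gamma, "gamma"),
             .checkRate(object@theta, "theta"))
    if (length(msg)) msg else TRUE
  })

setClass("CombinedModel", contains = "BreakageModel",
  representation(kappa = "numeric", gamma = "numeric", theta = "numeric"),
  validity = function(object) {
    msg <- c(.checkRate(object@kappa, "kappa"),
             .checkRate(object@gamma, "gamma"),
             .checkRate(object@theta, "theta"))
    if (length(msg)) msg else TRUE
  })

setClass("HotspotModel", contains = "BreakageModel",
  representation(kappaH = "numeric", kappaC = "numeric",
                 rHC = "numeric", rCH = "numeric"),
  validity = function(object) {
    msg <- c(.checkRate(object@kappaH, "kappaH"),
             .checkRate(object@kappaC, "kappaC"))
    if (length(object@rHC) != 1L || !is.finite(object@rHC) ||
        object@rHC <= 0 || object@rHC > 1)
      msg <- c(msg, "rHC must lie in (0, 1]")
    if (length(object@rCH) != 1L || !is.finite(object@rCH) ||
        object@rCH <= 0 || object@rCH > 1)
      msg <- c(msg, "rCH must lie in (0, 1]")
    if (!length(msg) && object@kappaH < object@kappaC)
      msg <- "kappaH must be >= kappaC (canonical labeling)"
    if (length(msg)) msg else TRUE
  })

#' @rdname BreakageModel
#' @export
OneCutModel <- function(kappa) new("OneCutModel", kappa = as.numeric(kappa))

#' @rdname BreakageModel
#' @export
TwoCutModel <- function(gamma, theta)
  new("TwoCutModel", gamma = as.numeric(gamma), theta = as.numeric(theta))

#' @rdname BreakageModel
#' @export
CombinedModel <- function(kappa, gamma, theta)
  new("CombinedModel", kappa = as.numeric(kappa), gamma = as.numeric(gamma),
      theta = as.numeric(theta))

#' @rdname BreakageModel
#' @export
HotspotModel <- function(kappaH, kappaC, rHC, rCH) {
  kappaH <- as.numeric(kappaH); kappaC <- as.numeric(kappaC)
  rHC <- as.numeric(rHC); rCH <- as.numeric(rCH)
  if (is.finite(kappaH) && is.finite(kappaC) && kappaH < kappaC) {
    # label-switching symmetry: swap states so hotspots are the faster ones
    tmp <- kappaH; kappaH <- kappaC; kappaC <- tmp
    tmp <- rHC; rHC <- rCH; rCH <- tmp
  }
  new("HotspotModel", kappaH = kappaH, kappaC = kappaC, rHC = rHC, rCH = rCH)
}

#' Truncated, normalized block size distribution
#'
#' A probability mass function over synteny block sizes (in genes) on a
#' finite support `[supportMin, supportMax]`, normalized to sum to one.
#' Produced by [truncatedPmf()] and consumed by [klDivergence()].
#'
#' @slot support integer vector of block sizes, contiguous and increasing.
#' @slot prob probabilities, same length as `support`, summing to 1.
#' @slot logProb natural-log probabilities, computed stably so that very
#'   small tail probabilities keep finite logs.
#' @aliases BlockSizePMF
#' @name BlockSizePMF-class
#' @export
setClass("BlockSizePMF",
  representation(support = "integer", prob = "numeric", logProb = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@support) == 0L)
      msg <- c(msg, "empty support")
    if (length(object@prob) != length(object@support) ||
        length(object@logProb) != length(object@support))
      msg <- c(msg, "support, prob and logProb must have equal length")
    if (any(object@prob < 0))
      msg <- c(msg, "negative probabilities")
    if (length(object@prob) && abs(sum(object@prob) - 1) > 1e-12)
      msg <- c(msg, "probabilities must sum to 1 within 1e-12")
    if (length(object@support) > 1L &&
        any(diff(object@support) != 1L))
      msg <- c(msg, "support must be contiguous integers")
    if (length(msg)) msg else TRUE
  })

#' Genome as a graph of gene-adjacency edges
#'
#' Chromosomes are paths of gene nodes; the inter-gene edges carry contiguous
#' integer indices `1..E0` across chromosomes. A breakpoint removes an edge;
#' synteny blocks at any time are the connected components (maximal runs of
#' genes joined by live edges).
#'
#' @slot chromosomeSizes integer, genes per chromosome.
#' @slot edgeChromosome integer of length `E0`, chromosome membership of
#'   each original edge.
#' @slot liveEdges logical of length `E0`; `FALSE` marks removed edges.
#' @aliases GenomeGraph
#' @name GenomeGraph-class
#' @export
setClass("GenomeGraph",
  representation(chromosomeSizes = "integer", edgeChromosome = "integer",
                 liveEdges = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@chromosomeSizes) == 0L ||
        any(object@chromosomeSizes < 1L))
      msg <- c(msg, "chromosomeSizes must be positive integers")
    e0 <- sum(pmax(object@chromosomeSizes - 1L, 0L))
    if (length(object@edgeChromosome) != e0)
      msg <- c(msg, "edgeChromosome length must equal sum(sizes - 1)")
    if (length(object@liveEdges) != e0)
      msg <- c(msg, "liveEdges length must equal sum(sizes - 1)")
    if (length(msg)) msg else TRUE
  })

#' Hotspot/coldspot labels for every original edge
#'
#' @slot labels integer of length `E0`: `1L` = hotspot, `2L` = coldspot.
#' @aliases SpotAssignment
#' @name SpotAssignment-class
#' @export
setClass("SpotAssignment",
  representation(labels = "integer"),
  validity = function(object) {
    if (length(object@labels) && !all(object@labels %in% c(1L, 2L)))
      "labels must be 1 (hotspot) or 2 (coldspot)" else TRUE
  })

#' Empirical block size distribution for one genome pair
#'
#' Observed synteny block size counts for a pair of genomes, truncated below
#' at `nMin` (sizes smaller than `nMin` are dropped before normalization)
#' and above at the largest observed size `nMax`, with probabilities
#' normalized over that range. Built with [empiricalPmf()].
#'
#' @slot pairId identifier of the genome pair.
#' @slot t evolutionary distance in mean amino-acid substitutions per site
#'   summed over both lineages.
#' @slot sizes observed block sizes (genes), increasing, all `>= nMin`.
#' @slot counts observed counts, same length as `sizes`.
#' @slot prob normalized probabilities at `sizes`.
#' @slot nMin,nMax truncation bounds actually applied.
#' @aliases EmpiricalPMF
#' @name EmpiricalPMF-class
#' @export
setClass("EmpiricalPMF",
  representation(pairId = "character", t = "numeric", sizes = "integer",
                 counts = "numeric", prob = "numeric", nMin = "integer",
                 nMax = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@sizes) == 0L)
      msg <- c(msg, "no block sizes survive the nMin cutoff")
    if (any(object@counts <= 0))
      msg <- c(msg, "counts must be positive")
    if (length(object@sizes) &&
        (min(object@sizes) < object@nMin || max(object@sizes) != object@nMax))
      msg <- c(msg, "sizes must lie in [nMin, nMax] with nMax attained")
    if (length(object@prob) && abs(sum(object@prob) - 1) > 1e-12)
      msg <- c(msg, "probabilities must sum to 1")
    if (length(object@t) != 1L || !is.finite(object@t) || object@t < 0)
      msg <- c(msg, "t must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' Result of fitting one model to one empirical distribution
#'
#' @slot modelId one of `"one_cut"`, `"two_cut"`, `"combined"`, `"hotspot"`.
#' @slot model the fitted [BreakageModel] (hotspot fits canonicalized to
#'   `kappaH >= kappaC`).
#' @slot kl minimized Kullback-Leibler divergence (nats).
#' @slot t evolutionary distance used.
#' @slot nMin,nMax truncation bounds of the fit.
#' @slot restartsConverged number of random restarts that converged.
#' @slot bestStartIndex index of the restart achieving the lowest divergence
#'   (ties broken by lowest index).
#' @aliases FitResult
#' @name FitResult-class
#' @export
setClass("FitResult",
  representation(modelId = "character", model = "BreakageModel",
                 kl = "numeric", t = "numeric", nMin = "integer",
                 nMax = "integer", restartsConverged = "integer",
                 bestStartIndex = "integer"),
  validity = function(object) {
    if (!is.finite(object@kl) || object@kl < -1e-9)
      "kl must be finite and non-negative" else TRUE
  })

#' Ensemble of independent breakage simulations
#'
#' Per-replicate synteny block size distributions from repeated stochastic
#' simulation of one model, with the across-replicate mean and standard
#' deviation of the empirical probability at each block size. Produced by
#' [runEnsemble()].
#'
#' @slot modelId generating model identifier.
#' @slot chromosomeSizes genome used.
#' @slot tMax simulated evolutionary distance (subs/site).
#' @slot support block sizes at which summaries are reported.
#' @slot mean,sd across-replicate mean and SD of empirical probability.
#' @slot replicateCounts list (one per replicate) of named integer count
#'   vectors, names = block size.
#' @aliases SimEnsemble
#' @name SimEnsemble-class
#' @export
setClass("SimEnsemble",
  representation(modelId = "character", chromosomeSizes = "integer",
                 tMax = "numeric", support = "integer", mean = "numeric",
                 sd = "numeric", replicateCounts = "list"),
  validity = function(object) {
    if (length(object@mean) != length(object@support) ||
        length(object@sd) != length(object@support))
      "summary vectors must match support length" else TRUE
  })
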