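#' @include AllClasses.R
NULL

#' Block size probability mass function of a breakage model
#'
#' Evaluates the analytical synteny block size distribution `P(n)` of a
#' model at block sizes `n` (in genes), for a pair of genomes separated by
#' evolutionary distance `t` (mean amino-acid substitutions per site summed
#' over both lineages). All four model PMFs condition on a cut at a
#' reference inter-gene region and give the probability that exactly `n`
#' genes remain in synteny before the next cut.
#'
#' @param model A [BreakageModel].
#' @param n Positive integer block sizes (vectorized).
#' @param t Evolutionary distance, non-negative.
#' @param log Return natural-log probabilities.
#' @return Numeric vector of (log) probabilities, one per element of `n`.
#' @seealso [truncatedPmf()] for the truncated/renormalized version used in
#'   fitting.
#' @export
setGeneric("blockSizePmf",
           function(model, n, t, log = FALSE) standardGeneric("blockSizePmf"))

#' @rdname truncatedPmf
#' @export
setGeneric("truncatedPmf",
           function(model, t, nMin, nMax) standardGeneric("truncatedPmf"))

#' @rdname modelId
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @rdname modelId
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' @rdname modelId
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname hotspotMachinery
#' @export
setGeneric("hotspotStationary",
           function(model) standardGeneric("hotspotStationary"))

#' @rdname hotspotMachinery
#' @export
setGeneric("hotspotConditionVector",
           function(model, t) standardGeneric("hotspotConditionVector"))

#' @rdname hotspotMachinery
#' @export
setGeneric("hotspotMatrices",
           function(model, t) standardGeneric("hotspotMatrices"))

#' @rdname consistencyDiagnostics
#' @export
setGeneric("overlapError",
           function(model, t) standardGeneric("overlapError"))

#' @rdname consistencyDiagnostics
#' @export
setGeneric("multicutError",
           function(model, t) standardGeneric("multicutError"))

#' @rdname breakpointRate
#' @export
setGeneric("breakpointRate",
           function(model, t, nSyntenicGenes, tMya)
             standardGeneric("breakpointRate"))

#' @rdname parameterSummaries
#' @export
setGeneric("hotspotFraction",
           function(model) standardGeneric("hotspotFraction"))
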