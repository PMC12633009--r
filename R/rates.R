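#' @include models.R
NULL

#' Breakpoint rate in breakpoints per million years
#'
#' Converts fitted model parameters into an expected number of breakpoints
#' per million years along the whole evolutionary path between the two
#' genomes. With `S` syntenic genes standing in for the number of ancestral
#' inter-gene regions and `tMya` the path length in millions of years:
#' the random-breakage rate is `kappa t S / tMya`; the correlated-breakage
#' rate `2 gamma t S / tMya` (each 2-cut event contributes two breakpoints);
#' the combined model adds the two, `(kappa + 2 gamma) t S / tMya`; and the
#' hotspot rate averages the two spot rates under the stationary law,
#' `(piH kappaH + piC kappaC) t S / tMya`.
#'
#' `tMya` is the full-path denominator. Divergence-time tables usually give
#' the one-way time to the last common ancestor; use [pathTimeMya()] to
#' double it.
#'
#' @param model A fitted [BreakageModel].
#' @param t Evolutionary distance (subs/site, both lineages summed).
#' @param nSyntenicGenes Total genes in synteny between the pair, `S`.
#' @param tMya Path length in millions of years (`> 0`).
#' @return Breakpoints per million years.
#' @examples
#' breakpointRate(TwoCutModel(gamma = 0.4, theta = 0.5), t = 0.25,
#'                nSyntenicGenes = 10000, tMya = 50)
#' @name breakpointRate
NULL

.checkRateInputs <- function(nSyntenicGenes, tMya) {
  if (nSyntenicGenes < 1) stop("nSyntenicGenes must be >= 1")
  if (!is.finite(tMya) || tMya <= 0) stop("tMya must be > 0")
}

#' @rdname breakpointRate
setMethod("breakpointRate", "OneCutModel",
  function(model, t, nSyntenicGenes, tMya) {
    .checkRateInputs(nSyntenicGenes, tMya)
    model@kappa * t * nSyntenicGenes / tMya
  })

#' @rdname breakpointRate
setMethod("breakpointRate", "TwoCutModel",
  function(model, t, nSyntenicGenes, tMya) {
    .checkRateInputs(nSyntenicGenes, tMya)
    2 * model@gamma * t * nSyntenicGenes / tMya
  })

#' @rdname breakpointRate
setMethod("breakpointRate", "CombinedModel",
  function(model, t, nSyntenicGenes, tMya) {
    .checkRateInputs(nSyntenicGenes, tMya)
    (model@kappa + 2 * model@gamma) * t * nSyntenicGenes / tMya
  })

#' @rdname breakpointRate
setMethod("breakpointRate", "HotspotModel",
  function(model, t, nSyntenicGenes, tMya) {
    .checkRateInputs(nSyntenicGenes, tMya)
    pi <- hotspotStationary(model)
    (pi[["H"]] * model@kappaH + pi[["C"]] * model@kappaC) * t *
      nSyntenicGenes / tMya
  })

#' Derived parameter summaries
#'
#' `meanGeometricSize(x)` is the mean of the unit-shifted geometric
#' distribution with exponential parameter `x`, `1 / (1 - exp(-x))` genes:
#' with `x = theta` it is the mean 2-cut span, with `x = kappaH t` the mean
#' distance between successive 1-cuts inside a hotspot. `hotspotFraction()`
#' is the stationary fraction of inter-gene regions that are hotspots,
#' `piH`. `spotLengthKb()` converts a Markov-chain transition probability
#' into a mean run length in kilobases (`1/r` consecutive inter-gene regions
#' times `kbPerGene`); `genesToKb()` is the plain gene-to-kilobase
#' conversion. The default conversion factor is 90 kb per gene.
#'
#' @param x Positive exponential parameter (e.g. `theta` or `kappaH * t`).
#' @param model A [HotspotModel].
#' @param r Transition probability in (0, 1] (`rHC` for hotspot runs, `rCH`
#'   for coldspot runs).
#' @param genes Number of genes (any non-negative real).
#' @param kbPerGene Kilobases per gene (default 90).
#' @return A number (genes, probability, or kilobases).
#' @examples
#' meanGeometricSize(0.5)       # ~2.54 genes
#' genesToKb(2.62)              # ~236 kb
#' spotLengthKb(0.05)           # 1800 kb mean hotspot length
#' @name parameterSummaries
NULL

#' @rdname parameterSummaries
#' @export
meanGeometricSize <- function(x) {
  if (any(is.na(x)) || any(x <= 0))
    stop("x must be > 0 (x = 0 gives an infinite mean)")
  1 / -expm1(-x)
}

#' @rdname parameterSummaries
setMethod("hotspotFraction", "HotspotModel", function(model)
  hotspotStationary(model)[["H"]])

#' @rdname parameterSummaries
#' @export
spotLengthKb <- function(r, kbPerGene = 90) {
  if (any(r <= 0) || any(r > 1)) stop("r must lie in (0, 1]")
  kbPerGene / r
}

#' @rdname parameterSummaries
#' @export
genesToKb <- function(genes, kbPerGene = 90) {
  if (any(genes < 0)) stop("genes must be non-negative")
  genes * kbPerGene
}

#' @rdname parameterSummaries
#' @param kb Kilobase value to round for display.
#' @details `kbRound()` rounds half away from zero (snapping to a `1e-9`
#'   grid first so floating-point representation error cannot flip a `.5`
#'   boundary); conversions such as 2.05 genes x 90 kb/gene = 184.5 kb
#'   display as 185 kb.
#' @export
kbRound <- function(kb) sign(kb) * floor(abs(round(kb, 9)) + 0.5)

#' @rdname breakpointRate
#' @param splitTimeMya One-way divergence time to the last common ancestor
#'   in millions of years.
#' @export
pathTimeMya <- function(splitTimeMya) {
  if (any(splitTimeMya <= 0, na.rm = TRUE)) stop("split time must be > 0")
  2 * splitTimeMya
}

#' Breakpoint rates for a table of fitted pairs
#'
#' Joins fit results with a divergence-time table and computes per-pair
#' breakpoint rates. `divergence` gives one-way split times, which are
#' doubled to the full-path denominator (recorded in the `t_mya_basis`
#' column).
#'
#' @param fitTable Data frame as produced by [fitSummary()] with columns
#'   `pair_id`, `model` and the parameter columns, plus `t_subs` and
#'   `n_syntenic_genes`.
#' @param divergence Data frame with columns `pair_id`, `split_time_mya`.
#' @return The fit table with `t_mya`, `t_mya_basis` and `rate_per_mya`
#'   columns appended; pairs without a divergence time get `NA`.
#' @export
breakpointRateTable <- function(fitTable, divergence) {
  stopifnot(all(c("pair_id", "model", "t_subs", "n_syntenic_genes") %in%
                names(fitTable)),
            all(c("pair_id", "split_time_mya") %in% names(divergence)))
  m <- match(fitTable$pair_id, divergence$pair_id)
  tMya <- ifelse(is.na(m), NA_real_,
                 pathTimeMya(divergence$split_time_mya[m]))
  rate <- vapply(seq_len(nrow(fitTable)), function(i) {
    if (is.na(tMya[i])) return(NA_real_)
    row <- fitTable[i, ]
    par <- switch(row$model,
      one_cut = row$kappa,
      two_cut = c(row$gamma, row$theta),
      combined = c(row$kappa, row$gamma, row$theta),
      hotspot = c(row$kappaH, row$kappaC, row$rHC, row$rCH))
    breakpointRate(makeModel(row$model, par), row$t_subs,
                   row$n_syntenic_genes, tMya[i])
  }, numeric(1))
  fitTable$t_mya <- tMya
  fitTable$t_mya_basis <- "2x split time"
  fitTable$rate_per_mya <- rate
  fitTable
}
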