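#' @include models.R
NULL

#' Build a genome adjacency graph
#'
#' Creates the initial genome graph: one path per chromosome, one node per
#' gene, and contiguous integer edge indices `1..E0` over the inter-gene
#' adjacencies (a chromosome of `s` genes contributes `s - 1` edges). All
#' edges start live; simulation removes them.
#'
#' @param chromosomeSizes Positive integers, genes per chromosome.
#' @return A [GenomeGraph].
#' @examples
#' g <- buildGenome(rep(1000L, 20))
#' nodeCount(g)  # 20000
#' edgeCount(g)  # 19980
#' @export
buildGenome <- function(chromosomeSizes) {
  if (length(chromosomeSizes) == 0L || any(chromosomeSizes < 1) ||
      any(chromosomeSizes != floor(chromosomeSizes)))
    stop("chromosomeSizes must be positive integers")
  sizes <- as.integer(chromosomeSizes)
  edgeChrom <- rep.int(seq_along(sizes), pmax(sizes - 1L, 0L))
  new("GenomeGraph", chromosomeSizes = sizes,
      edgeChromosome = as.integer(edgeChrom),
      liveEdges = rep(TRUE, length(edgeChrom)))
}

#' @rdname buildGenome
#' @param graph A [GenomeGraph].
#' @export
nodeCount <- function(graph) sum(graph@chromosomeSizes)

#' @rdname buildGenome
#' @export
edgeCount <- function(graph) length(graph@edgeChromosome)

#' @rdname buildGenome
#' @export
liveEdgeCount <- function(graph) sum(graph@liveEdges)

#' @rdname buildGenome
#' @export
chromosomeSizes <- function(graph) graph@chromosomeSizes

setMethod("show", "GenomeGraph", function(object) {
  cat(sprintf(
    "GenomeGraph: %d chromosomes, %d genes, %d/%d edges live\n",
    length(object@chromosomeSizes), nodeCount(object),
    liveEdgeCount(object), edgeCount(object)))
})

#' Assign hotspot/coldspot labels to inter-gene edges
#'
#' Samples a hot/cold label for every original edge, chromosome by
#' chromosome, from the two-state Markov chain of the hotspot model: the
#' first edge of each chromosome is drawn from the stationary distribution
#' and each subsequent edge follows the transition probabilities `rHC`,
#' `rCH`.
#'
#' @param graph A [GenomeGraph].
#' @param model A [HotspotModel].
#' @param seed Optional integer seed.
#' @return A [SpotAssignment].
#' @export
assignSpots <- function(graph, model, seed = NULL) {
  stopifnot(is(model, "HotspotModel"))
  if (!is.null(seed)) set.seed(seed)
  pi <- hotspotStationary(model)
  labels <- integer(edgeCount(graph))
  # flip probability depends on the current state, so runs are sequential
  # per chromosome; chromosomes are independent
  for (chrom in seq_along(graph@chromosomeSizes)) {
    idx <- which(graph@edgeChromosome == chrom)
    L <- length(idx)
    if (L == 0L) next
    u <- stats::runif(L)
    s <- if (u[1L] < pi[["H"]]) 1L else 2L
    chain <- integer(L)
    chain[1L] <- s
    if (L > 1L) {
      for (i in 2:L) {
        flip <- if (s == 1L) u[i] < model@rHC else u[i] < model@rCH
        if (flip) s <- 3L - s
        chain[i] <- s
      }
    }
    labels[idx] <- chain
  }
  new("SpotAssignment", labels = labels)
}

#' @rdname assignSpots
#' @param spots A [SpotAssignment].
#' @export
spotLabels <- function(spots) {
  factor(c("hotspot", "coldspot")[spots@labels],
         levels = c("hotspot", "coldspot"))
}

setMethod("show", "SpotAssignment", function(object) {
  cat(sprintf("SpotAssignment: %d edges (%d hot, %d cold)\n",
              length(object@labels), sum(object@labels == 1L),
              sum(object@labels == 2L)))
})

# per-original-edge cut rates for a simulation model
.edgeRates <- function(graph, model, spots) {
  if (is(model, "OneCutModel")) {
    rep(model@kappa, edgeCount(graph))
  } else if (is(model, "TwoCutModel")) {
    rep(model@gamma, edgeCount(graph))
  } else if (is(model, "HotspotModel")) {
    if (is.null(spots))
      stop("hotspot simulation requires a SpotAssignment")
    if (length(spots@labels) != edgeCount(graph))
      stop("SpotAssignment does not match this genome")
    ifelse(spots@labels == 1L, model@kappaH, model@kappaC)
  } else {
    stop("simulation supports one_cut, two_cut and hotspot models only")
  }
}

# apply cut events at the given original-edge indices; for the 2-cut model
# also remove the geometrically-spanned partner edge e' = e + n when it
# exists on the same ORIGINAL chromosome (current components are not
# consulted). Cuts on already-removed edges are no-ops.
.applyCuts <- function(graph, model, edges) {
  if (is(model, "TwoCutModel") && length(edges)) {
    if (model@theta <= 0) .degenerate("theta must be > 0 for 2-cut spans")
    span <- stats::rgeom(length(edges), prob = -expm1(-model@theta)) + 1L
    partner <- edges + span
    ok <- partner <= edgeCount(graph) &
      graph@edgeChromosome[pmin(partner, edgeCount(graph))] ==
        graph@edgeChromosome[edges]
    edges <- c(edges, partner[ok])
  }
  graph@liveEdges[edges] <- FALSE
  graph
}

#' Simulate genome breakage forward in time
#'
#' Event-driven forward simulation of breakpoint accumulation up to
#' evolutionary distance `tMax` (subs/site). Each original edge carries an
#' independent exponential clock with the model's cut rate; the next event
#' time is the minimum over the original edge set, implemented by
#' superposition (total rate `Lambda` = sum of edge rates, waiting times
#' `Exponential(Lambda)`, edge chosen proportional to its rate). A cut on an
#' already-removed edge advances time but changes nothing. Under the 2-cut
#' model every initial cut draws a span from [twoCutSpanPmf()] and also
#' removes the partner edge `e + span` when that edge exists on the same
#' original chromosome. Events whose time would exceed `tMax` are not
#' applied.
#'
#' @param graph A [GenomeGraph] (typically all edges live).
#' @param model A [OneCutModel], [TwoCutModel] or [HotspotModel].
#' @param tMax Positive evolutionary distance to simulate (subs/site).
#' @param spots A [SpotAssignment]; required for the hotspot model.
#' @param seed Optional integer seed.
#' @return The [GenomeGraph] at `tMax` (edges removed by breakage).
#' @examples
#' g <- simulateBreakage(buildGenome(rep(1000L, 20)), OneCutModel(0.1),
#'                       tMax = 0.25, seed = 1)
#' head(blockSizes(g))
#' @export
simulateBreakage <- function(graph, model, tMax, spots = NULL, seed = NULL) {
  if (tMax < 0) stop("tMax must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  rates <- .edgeRates(graph, model, spots)
  Lambda <- sum(rates)
  if (Lambda <= 0 || tMax == 0) return(graph)
  # count arrivals strictly inside [0, tMax] by accumulating waiting times
  nEvents <- 0L
  tNow <- 0
  repeat {
    w <- stats::rexp(256L, rate = Lambda)
    ct <- tNow + cumsum(w)
    k <- sum(ct <= tMax)
    nEvents <- nEvents + k
    if (k < 256L) break
    tNow <- ct[256L]
  }
  if (nEvents == 0L) return(graph)
  uniformRates <- length(unique(rates)) == 1L
  edges <- if (uniformRates) {
    sample.int(edgeCount(graph), nEvents, replace = TRUE)
  } else {
    sample.int(edgeCount(graph), nEvents, replace = TRUE, prob = rates)
  }
  .applyCuts(graph, model, edges)
}

# Reference implementation: literal per-edge exponential minima, resampled
# after every event. Distributionally identical to simulateBreakage() by
# memorylessness of the exponential; kept as a slow oracle for tests.
# @noRd
.simulateBreakageStepwise <- function(graph, model, tMax, spots = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- .edgeRates(graph, model, spots)
  if (sum(rates) <= 0 || tMax <= 0) return(graph)
  tNow <- 0
  repeat {
    dte <- stats::rexp(length(rates), rate = rates)
    dt <- min(dte)
    if (tNow + dt > tMax) break
    tNow <- tNow + dt
    graph <- .applyCuts(graph, model, which.min(dte))
  }
  graph
}

#' Synteny block sizes of a genome graph
#'
#' Sizes (in genes) of the maximal runs of genes joined by live edges. The
#' multiset always sums to the total gene count.
#'
#' @param graph A [GenomeGraph].
#' @return Integer vector of block sizes.
#' @export
blockSizes <- function(graph) {
  N <- nodeCount(graph)
  if (N == 1L) return(1L)
  sizes <- graph@chromosomeSizes
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  # left gene index of each edge, global numbering
  leftGene <- unlist(lapply(seq_along(sizes), function(chrom) {
    if (sizes[chrom] > 1L) offsets[chrom] + seq_len(sizes[chrom] - 1L)
    else integer()
  }), use.names = FALSE)
  joined <- rep(FALSE, N - 1L)
  joined[leftGene] <- graph@liveEdges
  diff(c(0L, which(!joined), N))
}

#' Run an ensemble of independent breakage simulations
#'
#' Repeats [simulateBreakage()] with deterministically derived per-replicate
#' seeds and summarizes the per-replicate empirical block size probabilities
#' (mean and standard deviation at each size). Under the hotspot model a
#' fresh spot assignment is drawn for every replicate.
#'
#' @param model A [OneCutModel], [TwoCutModel] or [HotspotModel].
#' @param tMax Evolutionary distance to simulate (subs/site).
#' @param replicates Number of independent simulations.
#' @param chromosomeSizes Genome specification (genes per chromosome).
#' @param seed Integer root seed; replicate seeds are derived from it.
#' @return A [SimEnsemble].
#' @examples
#' ens <- runEnsemble(OneCutModel(0.1), tMax = 0.25, replicates = 5,
#'                    chromosomeSizes = rep(200L, 4), seed = 1)
#' ens
#' @export
runEnsemble <- function(model, tMax, replicates = 100L,
                        chromosomeSizes = rep(1000L, 20), seed = NULL) {
  stopifnot(replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, replicates)
  genome <- buildGenome(chromosomeSizes)
  isHot <- is(model, "HotspotModel")
  repCounts <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(repSeeds[r])
    spots <- if (isHot) assignSpots(genome, model) else NULL
    gt <- simulateBreakage(genome, model, tMax, spots = spots)
    bs <- blockSizes(gt)
    tab <- tabulate(bs)
    keep <- which(tab > 0L)
    counts <- tab[keep]
    names(counts) <- keep
    repCounts[[r]] <- counts
  }
  support <- seq_len(max(vapply(repCounts,
                                function(x) max(as.integer(names(x))),
                                integer(1))))
  probs <- vapply(repCounts, function(x) {
    p <- numeric(length(support))
    p[as.integer(names(x))] <- x / sum(x)
    p
  }, numeric(length(support)))
  probs <- matrix(probs, nrow = length(support))
  new("SimEnsemble", modelId = modelId(model),
      chromosomeSizes = as.integer(chromosomeSizes), tMax = tMax,
      support = support, mean = rowMeans(probs),
      sd = if (replicates == 1L) numeric(length(support)) else
        apply(probs, 1L, stats::sd),
      replicateCounts = repCounts)
}

setMethod("show", "SimEnsemble", function(object) {
  cat(sprintf(
    "SimEnsemble: %d replicates of the %s model to t = %g subs/site\n",
    length(object@replicateCounts), object@modelId, object@tMax))
  cat(sprintf("  genome: %d chromosomes, %d genes; observed sizes 1..%d\n",
              length(object@chromosomeSizes), sum(object@chromosomeSizes),
              max(object@support)))
})

#' @rdname runEnsemble
#' @param ensemble A [SimEnsemble].
#' @export
ensembleSupport <- function(ensemble) ensemble@support

#' @rdname runEnsemble
#' @export
ensembleMean <- function(ensemble) ensemble@mean

#' @rdname runEnsemble
#' @export
ensembleSd <- function(ensemble) ensemble@sd

#' @rdname runEnsemble
#' @export
pooledBlockCounts <- function(ensemble) {
  all <- unlist(lapply(ensemble@replicateCounts, function(x) {
    rep(as.integer(names(x)), x)
  }), use.names = FALSE)
  tab <- table(all)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}
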