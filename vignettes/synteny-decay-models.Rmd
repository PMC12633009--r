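---
title: "Modeling synteny block size distributions: random, correlated and fragile breakage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling synteny block size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenyDecay)
```

## The modeling problem

A synteny block between two genomes A and B is a run of genes whose order
both genomes preserve; it marks a stretch of the ancestral genome that no
chromosomal rearrangement has disrupted in either lineage. As
rearrangements accumulate, blocks fragment, and the *distribution of
block sizes* (counted in genes) becomes an observable fingerprint of the
breakage process. `syntenyDecay` provides analytical block size
distributions for four breakage processes, a forward simulator to
validate them, divergence-based fitting, and interpretation of the fitted
parameters.

Throughout, evolutionary time is the rescaled distance `t`: the mean
number of amino-acid substitutions per site across homologs, summed over
the two lineages from their common ancestor. Breakpoints are assumed to
fall between genes; the physical length of inter-gene regions is ignored
(breakpoint counts depend only weakly on inter-gene size in mammals, so a
per-region rate is a reasonable approximation).

## The four models

All four distributions arise from the same construction: condition on a
cut at a reference inter-gene region, and compute the probability that
the next `n - 1` regions are uncut and the `n`-th is cut.

**1-cut (random breakage).** Cuts arrive independently in every region as
a Poisson process with rate `kappa`, so a region is cut within time `t`
with probability `q = 1 - exp(-kappa t)` and

$$P_1(n) = e^{-\kappa t (n-1)}\,(1 - e^{-\kappa t}),$$

the discrete analogue of the classical exponential law for random
breakage. One parameter.

**2-cut (correlated breakage).** Rearrangements such as inversions
introduce breakpoints in *pairs*: an initial cut (rate `gamma`) plus a
final cut `n` genes to its right, with the span geometric,
`p_F(n) = e^{-\theta(n-1)}(1-e^{-\theta})`. Because initial and final
cuts occur in equal numbers, conditioning on a cut means conditioning on
either type with probability 1/2; an initial cut can be ended by its own
partner or an independent initial cut, a final cut only by an independent
initial cut:

$$P_2(n) = \tfrac12 e^{-(\gamma t+\theta)(n-1)}(1-e^{-(\gamma t+\theta)})
        + \tfrac12 e^{-\gamma t (n-1)}(1-e^{-\gamma t}).$$

Two approximations are built in, each with a computable diagnostic:
spans that straddle the reference cut are neglected
(`overlapError()` $= (1-e^{-\gamma t})e^{-\theta}$), as are multiple
initial cuts in one region (`multicutError()`
$= 1 - e^{-\gamma t} - \gamma t e^{-\gamma t}$, the Poisson tail
`P(K >= 2)`). Small values of both mean a fitted model is internally
consistent. The exact span-dependent cut probability
`q(n) = 1 - e^{-(\gamma t + \theta)}(1 - (1-e^{-\gamma t})e^{-\theta n})`
can be written down, but its `n`-dependence is dropped (the
`overlapError()` diagnostic quantifies exactly the error of doing so);
the PMF always uses the `n`-independent form.

**1-cut + 2-cut.** Allowing both cut types gives a three-parameter
mixture with weights `gamma/(kappa+2gamma)` on the fast component and
`(kappa+gamma)/(kappa+2gamma)` on the slow one; it reduces to the 1-cut
model at `gamma = 0` and to the 2-cut model at `kappa = 0`
(`blockSizePmf()` reproduces both reductions to 1e-12, enforced by
tests).

**Hotspot (fragile breakage).** Breakpoint propensity varies along the
chromosome: regions are hotspots (1-cut rate `kappaH`) or coldspots
(`kappaC <= kappaH`), arranged by a two-state Markov chain with
transition probabilities `rHC` and `rCH` and stationary law
`piH = rCH/(rCH+rHC)`. Writing `T` for the transition matrix, `U`/`C`
for the per-state no-cut/cut probability matrices and `sigma` for the
probability that the conditioned-on cut is in a hot vs cold region,

$$P_{hs}(n) = \sigma\,(T \odot U)^{n-1}(T \odot C)\,\mathbf{1}.$$

`sigma` uses the exact exponential form
`(1-e^{-\kappa_H t})\pi_H / [(1-e^{-\kappa_H t})\pi_H +
(1-e^{-\kappa_C t})\pi_C]`; the rate-ratio form
`rCH kappaH / (rCH kappaH + rHC kappaC)` sometimes quoted is its
small-`kappa t` limit and is *not* used. The matrix power is evaluated by
`n - 1` successive row-vector-times-2x2 products (cost `O(n)` for a whole
PMF vector, with periodic rescaling in a compiled kernel so long blocks
never underflow); repeated matrix squaring would save nothing since the
fitting window needs every `n` anyway. An exhaustive oracle that sums
over all `2^{n+1}` hot/cold state sequences verifies the matrix form to
1e-12 in the test suite.

The hotspot model is label-symmetric: swapping the two states together
with their transition probabilities leaves every prediction unchanged.
Constructors therefore canonicalize to `kappaH >= kappaC` instead of
rejecting swapped input.

**Degenerate inputs.** A model whose parameters make a cut impossible
(`kappa t = 0`, `gamma t = 0`, both hotspot rates zero) has no
conditional block size distribution; constructors accept zero rates (they
are legitimate reduction limits) but PMF evaluation signals an error
rather than returning a defective distribution.

## The simulator

`buildGenome()` represents an ancestral genome as a graph: one node per
gene, chromosomes as paths, inter-gene edges indexed contiguously
`1..E0`. The default validation genome has 20 chromosomes of 1000 genes
(20,000 nodes, 19,980 edges). `simulateBreakage()` runs the breakage
process forward to `tMax`: every *original* edge carries an independent
exponential clock at its model rate, and the next event is the minimum
over all original edges — implemented by superposition (total rate
`Lambda`, waiting times `Exponential(Lambda)`, edge chosen proportionally
to its rate), which is distributionally identical; a test compares the
fast path against a literal per-edge-minima reference on a toy
chromosome. Design choices worth stating:

- Sampling stays over the original edge set; a cut landing on an
  already-removed edge advances time but changes nothing. This preserves
  the per-edge Poisson process the analytic models assume.
- Under the 2-cut model every event draws a span from the geometric span
  law and also removes the partner edge `e + n` iff that edge exists on
  the same *original* chromosome (current fragmentation is not
  consulted); partners always lie to the right.
- Hotspot simulations first label every edge by sampling the Markov
  chain along each chromosome, starting each chromosome from the
  stationary distribution (the chain's equilibrium is what the analytic
  `piH` assumes; a fixed initial state would bias short chromosomes).
- Events are applied while their time is at most `tMax`; an event whose
  time would exceed `tMax` is discarded.
- Block sizes are the connected-component sizes (maximal runs of genes
  joined by live edges); they always sum to the gene count.

`runEnsemble()` repeats this with per-replicate seeds derived
deterministically from one root seed and reports the mean and standard
deviation of the empirical probability at each block size. At
`t = 0.25` subs/site on the default genome the analytic PMFs of all
three simulated models sit well inside the mean ± 3 SD band wherever the
mean probability exceeds 1e-3. At shorter times (`t = 0.05`) the
simulated distributions retain a spike near whole-chromosome size that
the theory — which deliberately carries no information about the initial
chromosomes — cannot produce; the test suite asserts this deviation
rather than hiding it.

What the simulator deliberately does not emulate: gene gain and loss,
translocations or fusions (breakage only), circular chromosomes, unequal
chromosome sizes of real karyotypes, and the detection noise of real
microsynteny calling. Passing validation therefore shows the analytic
PMFs correctly describe their own generative process, not that real
genomes follow any of these models.

## Fitting

`empiricalPmf()` builds the observed distribution for one genome pair,
discarding blocks smaller than `nMin` (default 3 genes, matching the
minimum block size of upstream microsynteny callers, whose 1- and 2-gene
calls are unreliable) and renormalizing on `[nMin, NAB]`, `NAB` being
that pair's largest observed block — the same window on which model PMFs
are renormalized by `truncatedPmf()`. `fitModel()` minimizes

$$D_{KL}(\hat P \,\|\, P) = \sum_{n=n_{min}}^{N_{AB}}
  \hat P(n) \log \frac{\hat P(n)}{P(n; x)}$$

(natural log, `0 log 0 = 0`) over a parameter box — rates in
`[1e-8, 100]` sites/sub, transition probabilities in `[1e-8, 1]` — with
50 random restarts by default, each a bounded L-BFGS-B solve with
numerically estimated gradients, objective tolerance near machine
precision (`factr = 10`), and an iteration cap of 1000. Numerical
choices that matter:

- **Starting points** are drawn uniformly on the linear scale of each
  interval (a log-uniform option exists but is off by default).
- **Log-space solves.** Each local solve runs on log-transformed
  parameters with transformed bounds. With parameters spanning ten
  orders of magnitude, absolute finite-difference steps make gradients
  meaningless near the lower bound; the log transform makes them
  scale-free. Starting points are unchanged by this.
- **Model evaluation in log space.** Geometric terms are computed as log
  probabilities and normalized by log-sum-exp, so steep fits (large
  rates, distant `NAB`) yield finite divergences instead of underflowing
  to zero model mass; a model that truly assigns zero probability to an
  observed size gets `D_KL = +Inf` (returned, not raised) so line
  searches retreat, and the optimizer sees a large finite penalty.
- **Ties** among restarts are broken by lowest start index, making fits
  deterministic given the seed.
- **Identifiability of rates.** Every PMF depends on rates only through
  the products rate × `t`; rates are reported in sites/sub because `t`
  is supplied per pair. Without `t` only the products are estimable.

**The nested-model warm-start chain.** The four models are nested:
on the truncated window the 2-cut model at `theta` at its upper bound is
the 1-cut model, the combined model at `kappa` at its lower bound is the
2-cut model, and the hotspot model at `kappaH = kappaC` is the 1-cut
model — so each model's optimal divergence can never exceed that of the
model with one fewer parameter. Pure random multi-start does not reliably
realize this guarantee: the hotspot basin that reproduces a given
two-geometric mixture can be so small that tens of thousands of random
starts would be needed (observed on simulated data where ~400 restarts
were required once). `fitAllModels()` therefore fits models in order of
parameter count and appends to each model's random starts a few
deterministic warm starts that embed the previous optimum: the exact
embeddings above, plus, for the hotspot model, a one-parameter family of
constructions matching the eigenvalues of `T ⊙ U` to the fitted mixture
decay rates (with `kappaC` at its lower bound) scanned over `rCH` to
vary the mixture weight. Monotone descent from an embedded optimum can
only improve on it, so the nesting inequality holds numerically (to
optimizer slack) and not just in principle. `warmStart = FALSE` restores
fully independent fits.

**What is identifiable in the hotspot model.** Algebraically
`P_{hs}(n) = A\lambda_1^{n-1} + B\lambda_2^{n-1}` with `lambda_1,2` the
eigenvalues of the 2×2 matrix `T ⊙ U`: a three-degree-of-freedom family
generated by four parameters. A one-dimensional ridge of parameter
vectors therefore produces the *identical* block size distribution, and
the individual values of `kappaH`, `kappaC`, `rHC`, `rCH` cannot be
recovered from a block size distribution alone, no matter how much data.
The identifiable quantities are the mixture eigenvalues (and weight),
which the test suite shows are recovered from exact and simulated data;
interpretation of individual fitted hotspot parameters (hotspot
fraction, spot lengths) should be treated as one representative point on
that ridge. Parameter-recovery experiments fit simulator output with
`nMin = 1`, since truncation at 3 genes discards precisely the
short-block signal that pins the fast mixture component; the `nMin = 3`
convention is kept for real data where short calls are unreliable.

## Interpreting fitted parameters

`breakpointRate()` converts fitted rates into breakpoints per million
years along the whole inter-species path: `kappa t S / t_MYA` (1-cut),
`2 gamma t S / t_MYA` (2-cut; each event makes two breakpoints), their
sum for the combined model, and `(piH kappaH + piC kappaC) t S / t_MYA`
(hotspot), with `S` the pair's syntenic gene count standing in for the
number of ancestral inter-gene regions. The denominator `t_MYA` is the
*full path* in million years; divergence-time tables give one-way split
times, so `pathTimeMya()` doubles them and `breakpointRateTable()`
records that basis in its output. `meanGeometricSize(x) = 1/(1-e^{-x})`
gives mean 2-cut spans (`x = theta`) and mean within-hotspot inter-cut
distances (`x = kappaH t`); when such distances are aggregated across
many pairs the package reports per-pair values and leaves the
aggregation (median is recommended) to the caller. Physical lengths use
a constant 90 kb per gene (`genesToKb()`, `spotLengthKb()`); `kbRound()`
rounds half away from zero for display, so 184.5 kb prints as 185.

## Problem sizes and runtime

The shipped validation protocol uses the 20 × 1000-gene genome with
50-replicate ensembles for band tests and parameter recovery, 20
single-replicate datasets for the nesting check, and 100 random
parameter draws for the enumeration oracle at `n <= 12`; with these
sizes the full test suite and the acceptance script each run in a few
minutes on one CPU. Larger ensembles sharpen the recovery checks but do
not change any conclusion.

## Known limitations

- All models condition on at least one breakpoint and assume `t` large
  enough that initial chromosome sizes are forgotten; fits at very small
  `t` inherit the long-block bias shown by the short-time simulations.
- Overlapping 2-cut spans are handled approximately (see the
  diagnostics); regimes with `overlapError()` near 1 need an exact
  treatment the package does not provide.
- Genome pairs sharing evolutionary history are not independent; no
  phylogenetic correction is attempted, and fitted per-pair parameters
  should not be treated as independent samples.
- Block sizes are gene counts; no centimorgan or base-pair variant of
  the models is provided beyond the constant kb-per-gene display
  conversion.
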