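# syntenyDecay

Models of synteny block size distributions for pairwise genome comparison.

When two genomes are compared, the sizes of their shared microsynteny
blocks (runs of genes in conserved order, measured in genes) carry a
record of how chromosomal rearrangements accumulated since the two
lineages split. `syntenyDecay` implements four analytical models of that
process, a stochastic simulator to validate them, and machinery to fit
them to observed block size tables. It is aimed at comparative genomicists
who have per-pair block size distributions (e.g. from a microsynteny
caller) and want to ask which breakage process explains them, and at
modelers who need a calibrated null model of synteny decay.

## The models

All models place breakpoints ("cuts") in inter-gene regions of an
ancestral genome over an evolutionary distance *t*, measured as the mean
amino-acid substitutions per site summed over both lineages. Conditioning
on a cut at a reference region, the probability that exactly *n* genes
remain in synteny is:

- **1-cut (random breakage)** — cuts arrive uniformly at rate κ:
  `P1(n) = e^{-κt(n-1)} (1 - e^{-κt})`, a geometric distribution.
- **2-cut (correlated breakage)** — breakpoint *pairs* mimicking
  inversions: an initial cut at rate γ plus a partner cut a geometrically
  distributed span away (`p(n) = e^{-θ(n-1)}(1 - e^{-θ})`). Conditioning
  on either member of the pair with probability 1/2:
  `P2(n) = ½ e^{-(γt+θ)(n-1)}(1-e^{-(γt+θ)}) + ½ e^{-γt(n-1)}(1-e^{-γt})`.
- **1-cut + 2-cut** — both cut types, with mixture weights
  `γ/(κ+2γ)` and `(κ+γ)/(κ+2γ)`.
- **Hotspot (fragile breakage)** — 1-cuts at rate κH in hotspots and κC
  in coldspots, with hot/cold labels laid along the chromosome by a
  two-state Markov chain (transition probabilities rHC, rCH):
  `Phs(n) = σ (T⊙U)^{n-1} (T⊙C) 1`, where T is the transition matrix, U
  and C hold per-state no-cut and cut probabilities, and σ is the
  probability that the conditioned-on cut sits in a hot vs cold region.

Models are fitted per genome pair by minimizing the Kullback–Leibler
divergence between the empirical distribution and the model PMF, both
truncated and renormalized on `[nmin, NAB]` (`nmin = 3` by default, `NAB`
the largest observed block), using bounded multi-start quasi-Newton
optimization. Fitted parameters convert into interpretable quantities:
breakpoint rates per million years, the hotspot fraction of the genome,
mean hotspot/coldspot lengths, and mean inversion spans in genes or kb.

## A worked example

Simulate correlated breakage on a 20-chromosome, 20,000-gene ancestral
genome, then fit all four models to the simulated block sizes:

```r
library(syntenyDecay)

truth <- TwoCutModel(gamma = 0.1, theta = 0.5)
ens <- runEnsemble(truth, tMax = 0.25, replicates = 50, seed = 7)
emp <- empiricalPmf(pooledBlockCounts(ens), t = 0.25, nMin = 3,
                    pairId = "simulated")
emp
#> EmpiricalPMF 'simulated': 275 block sizes on [3, 381], 31556 blocks, t = 0.25

fits <- fitAllModels(emp, restarts = 50, seed = 11)
round(sapply(fits, klDiv), 6)
#>  one_cut  two_cut combined  hotspot
#> 0.176224 0.005557 0.005557 0.005477

fits$two_cut
#> FitResult: two_cut model, D_KL = 0.00555735 nats
#>   gamma = 0.103021, theta = 0.474299
#>   fitted on [3, 381] at t = 0.25; 48 restarts converged
```

The 1-cut model misses badly (it cannot produce the excess of short
blocks that paired breakpoints create), while the 2-cut fit recovers the
generating rate γ ≈ 0.1 and span decay θ ≈ 0.5. The implied mean 2-cut
span and an illustrative breakpoint rate:

```r
meanGeometricSize(0.4743)           # 2.648 genes per inversion span
kbRound(genesToKb(2.648))           # ~238 kb at 90 kb per gene
breakpointRate(fittedModel(fits$two_cut), t = 0.25,
               nSyntenicGenes = 20000, tMya = pathTimeMya(50))
#> 10.3 breakpoints per million years over the whole path
```

A command-line interface over the same functions is installed at
`inst/scripts/synteny-decay` with subcommands `simulate`, `fit`,
`compare`, `rates`, `diagnostics` and `fixtures`.

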