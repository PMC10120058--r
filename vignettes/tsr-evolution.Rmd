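---
title: "Standing variation versus de novo mutation in herbicide target-site resistance: models and methods"
author: "herbisweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standing variation versus de novo mutation in herbicide target-site resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Target-site resistance (TSR) to herbicides arises through a handful of
codon substitutions in the genes encoding the targeted enzymes — for
ACCase-inhibiting herbicides in blackgrass (*Alopecurus myosuroides*),
seven nucleotide positions account for the known resistance alleles.
When a field population becomes resistant within a couple of decades,
two genetic routes are possible: the resistant alleles were already
segregating before herbicides were introduced (standing genetic
variation, SGV), or they arose by new mutation after selection began
(de novo). The two routes leave different footprints — soft sweeps with
several resistant haplotypes of independent origin versus hard sweeps
of a single haplotype — and they imply different management outlooks.

`herbisweep` implements the quantitative machinery for this question:

* a diploid Wright–Fisher forward simulator of a herbicide-target locus
  with origin-tracked TSR mutations (`runBurnin()`,
  `runSelectionPhase()`, `runReplicates()`);
* closed-form probabilities of adaptation from standing variation and
  from de novo mutation (`probSGV()`, `probDeNovo()`,
  `probAdaptTotal()`, `fractionSGV()`);
* replicate classification and aggregation (`classifyReplicate()`,
  `aggregateReplicates()`, `neutralCensus()`);
* population-genetic summaries (`wattersonTheta()`,
  `nucleotideDiversity()`, `neFromTheta()`, `chi2Yates()`);
* amplicon-haplotype utilities that call TSR codons, deduplicate
  haplotypes and count independent mutational origins (`callTSR()`,
  `dedupeHaplotypes()`, `shared2x2()`, `countOrigins()`), exercised on
  synthetic panels with machine-readable truth (`generatePanel()`,
  `makeFixtureSuite()`).

# The simulation model

## Locus template and fitness effects

The locus is a 12,250-bp ACCase-like gene model (`buildTemplate()`):
exons of equal size separated by introns and flanked by noncoding
sequence, with a configurable coding fraction, and seven TSR target
nucleotides placed inside exons. Coordinates are 0-based and half-open;
site classes are exhaustive with precedence
`tsr_target > exonic > noncoding`. The true ACCase exon count and
coding fraction are not part of the shipped defaults (`nExons = 10`,
`codingFraction = 0.5` are generic placeholders); users modelling a
real gene should supply `exonIntervals` from an annotation.

New mutations draw their effects from `dfeConfig()`: intron and
intergenic mutations are neutral; exonic mutations are neutral with
probability 0.25 and otherwise deleterious with `s = -G`,
`G ~ Gamma(shape = 0.245, mean = 1.54e-4)` and codominance
(`h = 0.5`). The stated mean is interpreted as the mean of the
*deleterious class itself*, not of all exonic mutations — the
distribution is attached to the deleterious draws. Mutations at the
seven TSR nucleotides carry `tsrSBefore` (0 by default: resistance
alleles are neutral until herbicide use begins). Setting
`pNeutralExon = 1` gives the fully neutral model variant.

## Wright–Fisher dynamics

Each replicate starts from a mutation-free population of `N` diploids
and runs a burn-in of `10 N` generations to mutation–selection–drift
balance, followed (when `herbicideOn = TRUE`) by 30 generations of
herbicide selection. One generation consists of:

1. **Viability selection.** Parental sampling weights are
   multiplicative across sites — 1, `1 + hs`, `1 + s` for the three
   genotypes. During the selection phase the weight of any individual
   carrying at least one TSR allele is additionally multiplied by
   `survivalRatio` (default 20); resistance is fully dominant.
2. **Reproduction.** Each of the `2N` offspring gametes draws a parent
   with probability proportional to its weight (soft selection; the
   population size never changes), then a meiosis with
   `Poisson(r (L-1))` crossovers at uniform breakpoints and
   `Poisson(mu L)` new mutations at uniform sites.

Every mutation event receives a fresh origin id, so recurrent hits at
the same nucleotide remain countable as independent origins, and every
TSR record keeps its origin generation (`<= 0` burn-in, `>= 1`
selection). During the selection phase the frequency of every
segregating TSR origin is recorded each generation.

Per-site defaults are the maize rates `mu = 3.0e-8` and
`r = 7.4e-9`, with `N = 42,000` (the highest diversity-based estimate
for blackgrass field populations) or `84,000` (its doubling, since
diversity-based estimates integrate over bottlenecks and are
conservative).

## Population rescaling

Simulating `N = 42,000` for 420,000 generations is not desk-scale;
`rescaleConfig(config, lambda)` applies the standard rescaling
`N' = N/lambda`, `mu' = mu * lambda`, `r' = r * lambda`, with drawn
selection coefficients multiplied by `lambda`, so `N mu`, `N r` and
`N s` are invariant. Two quantities deliberately do not scale: the
selection phase stays 30 generations (it is a fixed window of the
model, not a scaled time), and `survivalRatio` stays 20 (a bounded
viability ratio, not a small coefficient). Rescaling is not exact for
every observable: the amount of standing variation scales with
`log(2N)`, so a `lambda = 20` run carries slightly less standing TSR
variation than the full-size protocol — the package's checks therefore
allow a few percentage points of rescaling slack on origin
proportions, and a rescaling-invariance test (`lambda` 2 versus 4 on a
smaller baseline) guards the implementation itself.

## Replicate classification

`classifyReplicate()` looks at TSR origins present in the final
selection generation at or above a threshold frequency (default one
copy, `1/(2N)` — the most literal reading of "present"): if any
surviving origin predates selection the replicate is `sgv` (runs mixing
standing and de novo origins count as SGV), if all surviving origins
arose during selection it is `de_novo_only`, otherwise `none`. A TSR
allele that drifted to fixation during the burn-in counts as standing
variation at frequency 1: the population is genuinely resistant before
selection starts, and hiding such runs would bias the SGV proportion
downward. `aggregateReplicates()` turns a replicate set into the three
proportions, the histogram of independent origins per run, and
per-class mean frequency trajectories. `neutralCensus()` samples
burn-ins with selection switched off to count how many TSR origins
segregate simultaneously under pure drift.

## A note on the strength of herbicide selection

The literal reading of the selection regime — carriers of one or more
TSR alleles have a 20-fold higher chance of surviving each herbicide
application — makes establishment essentially certain: a single
resistant copy expects about 20 surviving descendants per generation,
so almost no TSR lineage that exists (or arises) during the selection
phase is lost. Under this model the expected number of de novo TSR
arrivals in the 30-generation window is `2 N mu * 7 * 30 ~ 0.5`
independently of rescaling, so an appreciable fraction of replicates
ends with de-novo-origin alleles present, and resistant lineages sweep
within a handful of generations. Weaker effective selection (for
example a few percent per generation) would instead produce slow
trajectories and frequent stochastic loss of new mutations. Both
regimes are reachable through `survivalRatio`; the package default
follows the literal 20-fold reading, and the analytic module lets users
explore the full range of beneficial coefficients.

# Analytic sweep probabilities

With `Theta = 4 Ne u * targetSize`, `alpha_b = 4 Ne h_b s_b` and
`alpha_d = 4 Ne h_d s_d`:

* `probSGV()`: the probability that at least one copy of the standing
  variation at onset escapes drift,
  `P_sgv = 1 - exp(-Theta * log(1 + alpha_b / (alpha_d + 1)))`. The
  prior deleterious pressure `s_d` lowers standing frequencies and
  enters only through `alpha_d`.
* `establishmentProb()`: the diffusion fixation probability of a single
  new copy, `(1 - e^{-2hs}) / (1 - e^{-4 Ne h s})`, with the neutral
  limit `1/(2Ne)` taken analytically.
* `probDeNovo()`: `P_dn = 1 - exp(-2 Ne u * targetSize * T * pi_est)`
  for mutations arising during the `T`-generation window.
* `probAdaptTotal()` combines the two routes assuming independence;
  `fractionSGV()` is the conditional probability `P_sgv / P_total`
  that adaptation, given that it happens, stems from standing
  variation.

"Adaptation" here means establishment (escape from stochastic loss),
matching the 30-generation horizon, not completed fixation. The
dominance coefficients default to 0.5 on both sides; both the
unconditional `P_sgv` and the conditional fraction are reported, with
the conditional fraction used for headline statements.
`gridEvaluate()` tabulates everything over log-spaced grids
(`s_ben` in 0.01–1, bracketing weakly beneficial to lethal-to-
susceptibles selection; `s_del` in 1e-6–1e-2). These closed forms are
approximations — the test suite validates them against the forward
simulator at small `Ne`, in a parameter regime (mild dominant benefit)
where diffusion and branching-process pictures agree.

# Amplicon typing and origin counting

The typing module consumes phased amplicon haplotypes (FASTA headers
`sampleID|populationID|gene|phase`). `callTSR()` anchors each
haplotype to a reference by global pairwise alignment (a fast path
skips alignment for ungapped, equal-length input), translates the
codons listed in a codon table (ACCase 1781/1999/2027/2041/2078, ALS1
197/574 by default), and reports each codon as wild type, resistant,
or — when gaps or ambiguous bases intersect the codon — `uncallable`,
never silently wild type. `dedupeHaplotypes()` groups exact sequences
(after uppercase/gap normalisation, mirroring "nonredundant
haplotypes") and annotates sharing across populations;
`shared2x2()` cross-tabulates TSR status against sharing for
`chi2Yates()`.

`countOrigins()` operationalises the distinction between recurrent
mutation and recombinational transfer within a field: carriers of a
TSR mutation are grouped into backbones (sequences compared with the
mutated codon masked; single linkage at `kBackbone = 3` differing
sites, a guard against sequencing noise), and a backbone is downgraded
to `putative_recombinant` when its sequence is exactly a
single-breakpoint mosaic of an observed TSR haplotype and an observed
wild-type haplotype (exhaustive breakpoint scan, both orientations).
The largest backbone is never downgraded, so an observed mutation
always has at least one independent origin. This parsimony rule is a
design choice validated on synthetic truth only: on real data a mosaic
explanation and an independent origin can be genuinely
indistinguishable.

The bundled references (`mockReference()`) are deterministic 2-kb
synthetic sequences carrying the real reference codons
(Ile/Trp/Trp/Ile/Asp; Pro/Trp) at scaled coordinates — enough to
exercise every codon-calling path without shipping a 13.2-kb amplicon.
They are labelled synthetic throughout and are not the real gene
sequences.

# Synthetic panels

`generatePanel()` builds haplotype panels by a fixed-divergence star
design: every backbone carries its own disjoint set of private
substitutions, so planted pairwise divergences are realised exactly;
TSR events apply minimal-change codon substitutions on chosen
backbones; recombinants are exact single-crossover mosaics; a sharing
structure assigns clusters to populations. The generator emulates what
the typing logic depends on — differing-site counts, breakpoints,
sharing — and deliberately not what it does not: there is no
coalescent genealogy, no linkage-disequilibrium decay, no sequencing
error and no indels. Passing the truth-recovery tests therefore shows
that the typing logic is correct on unambiguous input, not that real
panels are unambiguous. `makeFixtureSuite()` writes the canned inputs
used by the test suite, including a 250-cluster panel whose
shared-versus-private table is (TSR 20/42, wild type 55/133) by
construction.

# Numerical and implementation choices

* **Engines.** The default `linked` engine is the exact
  haplotype-based model, implemented in C++: sparse mutation lists
  with copy-on-write sharing, a Walker alias table (or, while the
  weight spread is mild, rejection sampling) for fitness-proportional
  parent choice, and an internal xoshiro256++ stream seeded from R's
  RNG so `set.seed()` gives bitwise reproducibility. The `freq` engine
  evolves every mutation as an independent biallelic locus (selection
  on Hardy–Weinberg genotype frequencies, binomial resampling); it
  ignores linkage and serves as a fast semi-independent cross-check.
* **Effectively neutral effects.** Deleterious mutations with
  `|2 N s| < 0.1` are recorded with their drawn coefficients but
  skipped in fitness bookkeeping: drift dominates such effects by an
  order of magnitude, and the approximation error on any individual's
  weight is below `1e-5` while the per-generation sampling noise is of
  order `1/sqrt(2N)`. TSR effects always count, whatever their size.
* **Bookkeeping.** Lost and fixed mutations are swept from the
  haplotype lists every `pruneEvery` generations (default 150). Fixed
  non-TSR mutations multiply every weight by the same constant between
  sweeps, so dynamics are unchanged — the interval is purely a
  performance knob (runs are bitwise identical across intervals).
  Fixed TSR alleles are never pruned and stay visible at frequency 1.
* **Degenerate inputs.** `mu = 0` burn-ins return empty registries;
  monomorphic populations without mutational input terminate early
  (trajectories of fixed TSR lineages are padded at frequency 1);
  zero marginals make the chi-squared test error rather than return
  `NaN`; codons that cannot be read are `uncallable`.
* **Problem sizes.** The package's own test suite runs the replicate
  protocol at `lambda = 20` with 120 replicates, the neutral-fixation
  check with 20,000 trials at `N = 50`, stationarity over 50 burn-ins
  at `N = 500`, the analytic-versus-simulation comparison with 300
  replicates at `N = 500`, rescaling invariance at `lambda` 2 versus 4
  around an `N = 800` baseline, and the neutral census with 15
  rescaled replicates; the acceptance script runs the full
  200-replicate set. These sizes are the package's choice of a
  desk-scale experiment; all statistical tolerances are three standard
  errors at the realised sizes.

# Limitations

* No spatial structure, seed bank, selfing, migration or
  metapopulation dynamics, and no polygenic (non-target-site)
  resistance — the model is a single panmictic field.
* Finite-sites mutation allows recurrent hits; at the default rates
  collisions are negligible, but boosted-rate test configurations
  slightly deflate site-based diversity estimators relative to
  infinite-sites theory.
* The analytic module inherits the usual diffusion and independence
  approximations; it is validated against simulation only in the
  regimes the tests cover.
* Recombinant detection is a parsimony heuristic over observed
  sequences; it cannot prove independence of origin.
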