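---
title: "Methods: archaic EPAS1 haplotype analysis in himalhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archaic EPAS1 haplotype analysis in himalhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(himalhap)
```

## The scientific problem

Tibetans, Sherpa and several other Himalayan peoples tolerate chronic
hypoxia in ways lowlanders do not, and much of that tolerance maps to
*EPAS1*, a transcription factor of the hypoxia-inducible-factor pathway.
Within an intronic ~32-kb stretch of *EPAS1*, highland genomes carry a
haplotype that closely matches the genome of an archaic Denisovan
individual — the signature of archaic introgression followed by positive
selection. The empirical core of the analysis is a five-SNP motif
(rs115321619, rs73926263, rs73926264, rs73926265, rs55981512) whose
derived-allele configuration spells "AGGAA"; a phased chromosome that is
derived at all five positions is a *core-haplotype carrier*.

`himalhap` implements the full computational pathway for studying this
system from a multiplexed SNP panel: genotype quality control, statistical
phasing, core-haplotype frequency estimation and its correlation with
residence altitude, median-joining haplotype networks, Bayesian inference
of scaled selection coefficients under Wright's island model, genotype–
altitude association under three genetic codings, and forward simulation
of the proposed selection scenario. A synthetic-data generator reproduces
the statistical structure of such a survey so that every stage is testable
without any external data.

## The data model

A `genotype_panel` couples an ordered locus table (ancestral/derived
alleles assigned from a primate alignment, supplied as configuration), a
sample table (population code, reported and genotype sex, amplification
and duplicate flags) and a samples × loci matrix of derived-allele dosages
in {0, 1, 2, NA}. Dosages count **derived** alleles, not ALT or minor
alleles, because every downstream statistic (the core motif, frequency
profiles, the island model) is defined on ancestral/derived polarity; the
VCF reader therefore re-orients records whose REF allele is the derived
one.

Only nine of the study panel's 19 locus identifiers are public, and the
ancestral/derived bases of the assay are not published; the default panel
(`default_panel()`) fills the gaps with clearly-labelled synthetic
placeholders (ids prefixed `syn_`). This affects nothing downstream: all
statistics operate on the 0/1 encoding, and a laboratory using the real
assay would supply its own locus table.

Altitude classes follow the study's stratification — high above 3000 m,
low below 2000 m, medium in the closed interval [2000, 3000] so the three
classes partition the line. The boundary values 2000 and 3000 are assigned
to medium, the reading that matches the printed inequalities with minimal
reinterpretation.

## The synthetic survey generator

`simulate_panel()` draws each chromosome as the core haplotype with
probability `core_freq_fn(altitude)` and otherwise from a weighted set of
background haplotypes, then adds missing calls, duplicate samples
(re-genotyped copies with independent missingness) and sex-discordant
samples. Simulation is at the haplotype level so that phasing can be
scored against ground truth. Default conditions mirror the survey design:
populations spanning 86–4550 m; a logistic frequency–altitude map rising
from ~2% near sea level towards 0.8 above 4000 m (matching the observed
range of core-haplotype frequencies, from 0 in lowland groups to 78% in
the highest-dwelling population); four background haplotypes at least six
mutational steps from the core cluster, echoing the observed six-mutation
cluster separation.

What the generator does *not* emulate: recombination (one observed
haplotype is plausibly a recombinant carrying the motif on a background
flank), genotyping error (duplicate concordance in real data is ~98%, here
exactly 100% because duplicates differ only in missingness), population
structure beyond the altitude gradient, and mutation. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed generative structure, not robustness to these real-data features.

## QC

Filters run in a fixed order — sex-discordance, then sample missingness
(strictly more than 20% missing calls), then SNP missingness — and the
composition is idempotent. Genotype sex is an input column, not inferred:
the panel is autosomal, and the original sex check used assay-external
information. Concordance between duplicate pairs excludes calls missing on
either side from the denominator, the convention that makes the statistic
independent of the missingness rate.

## Phasing by EM

`em_phase()` maximises the multinomial random-pairing likelihood
$L(f) = \prod_s \sum_{(h,k)\,\text{compatible}} c_{hk} f_h f_k$ (with
$c_{hk}=2$ for $h \ne k$) by expectation–maximisation over haplotype
frequencies — the classic gene-counting estimator. This is a deliberate,
deterministic stand-in for coalescent-informed phasing software: at 19
tightly linked SNPs with strong LD between two divergent clusters, the
multinomial model is adequate, and determinism buys exact testability
(monotone likelihood ascent, order invariance, brute-force optimality on
small instances). Missing genotypes are handled by summing over both
dosage completions. Each sample's enumeration cost is $h + 2m$ doublings
($h$ heterozygous, $m$ missing sites); samples above a cost of 20 raise an
error advising locus windowing, since each missing site doubles the
enumeration twice (once per chromosome). Initial frequencies weight
unambiguous completions, with a $10^{-6}$ floor keeping every compatible
haplotype reachable; seeded random restarts are available and used in the
optimality tests. Best-pair assignment maximises $f_h f_k$, with ties
broken by the lexicographically smallest pair. Exact haplotype counts
reported for the original study (95 phased haplotypes) are tool- and
seed-dependent and are treated as approximate references, not targets.

Phasing accuracy against synthetic truth is measured by `switch_error()`,
counting incorrectly phased adjacent heterozygous junctions; on panels
with the default two-cluster LD structure the EM stand-in phases with
essentially zero switch error.

## Core frequencies and the altitude correlation

`pop_core_frequencies()` counts motif-carrying chromosomes per population
from hard best-pair assignments (two per retained sample), matching
count-based reporting; a posterior-weighted variant is available.
`altitude_correlation()` is Spearman rank correlation with midrank ties.
The p-value uses the t approximation, which at the study's scale (~55
populations) reproduces the printed order of magnitude; for eight or fewer
populations an exact permutation p-value is computed by full enumeration
(8! orderings; beyond that the enumeration cost outgrows the approximation
error, which is already ~10^-3^ at n = 9).

`shared_variant_filter()` implements the candidate-functional-variant
logic: report loci whose derived allele is carried by the archaic
reference, fixed among carrier haplotypes, and absent from all
non-carriers. Its output shrinks monotonically as non-carrier evidence
accumulates.

## Median-joining networks

`median_joining()` builds the haplotype network in the median-joining
style for binary states: start from the minimum spanning network (an edge
is kept when its length does not exceed the pair's minimax connection
threshold plus a relaxation ε, default 0), then repeatedly add unobserved
*median vectors* — position-wise majority consensuses of node triplets —
when they reduce the total network cost (the minimum-spanning-tree weight
of the node set), finally discarding medians whose removal leaves the cost
unchanged. Two design choices depart from a naive greedy reading. First,
the candidate pool is the *iterated* majority closure, because an optimal
Steiner point can be the median of a triplet involving other medians.
Second, candidates are added in jointly evaluated batches of up to four on
compact node sets (≤ 12 nodes): a Steiner point frequently pays off only
together with another, and an optimal Steiner tree on six terminals needs
at most four Steiner points. With these choices the construction attains
the exact minimum Steiner-tree cost — verified against a Dreyfus–Wagner
dynamic programme over the full hypercube on 160 random small instances —
while larger networks fall back to single-candidate greedy additions.
Ties are always broken towards the lexicographically smallest allele
string, making the output deterministic. An optional pruning pass
(maximum-parsimony style) removes medians lying on no shortest
observed-to-observed path. `cluster_partition()` splits nodes by
core-motif carriage and reports the minimum cross-partition Hamming
distance — six mutations for haplotypes shaped like the published
carrier/non-carrier pair.

## Island-model selection inference

The stationary density of the derived-allele frequency in deme $i$ at
locus $j$ under migration–drift–selection is
$$\pi(p) \propto p^{M\tilde\pi - 1} (1-p)^{M(1-\tilde\pi) - 1} e^{\sigma p},$$
with $M$ the scaled migration rate, $\tilde\pi$ the migrant-pool
frequency, and $\sigma = 2N_e s$ the scaled selection coefficient (genic
kernel, the minimal form consistent with reporting selection as
$\sigma = 2N_e s$). The normalising constant is
$B(a,b)\,{}_1F_1(a; a+b; \sigma)$ with $a = M\tilde\pi$,
$b = M(1-\tilde\pi)$; the confluent hypergeometric series is evaluated by
log-sum-exp so the density remains usable at $\sigma$ of order 100, where
naive quadrature of $e^{\sigma p}$ overflows. Quadrature serves as the
independent normalisation oracle in the tests.

`fit_selection()` samples the joint posterior by component-wise
Metropolis-within-Gibbs: binomial likelihood for the allele counts,
logit-scale walks for $p_{ij}$ and $\tilde\pi_j$, a reflected walk for
$\sigma_{ij} \ge 0$ with an Exponential($\delta_j$) prior whose rate gets
a conjugate Gamma hyper-prior (Gibbs update), and a log-scale walk for $M$
with a log-uniform prior on [0.1, 1000]. Short pilot runs adapt proposal
widths towards 25–45% acceptance. Defaults mirror the original run plan
(25 pilot runs of 1000, burn-in 25000, thinning 25); tests and the demo
pipeline use shorter, documented settings. Posterior summaries carry a
crude autocorrelation-based effective sample size, with a warning (not a
failure) below 50.

A known limitation at small scale: with few demes and loci, $M$ and the
one-sided $\sigma$ are only weakly jointly identified — under null data
the sampler tends to trade a too-large $M$ against inflated $\sigma$
upper bounds. The validation suite therefore checks the null-shrinkage
property conditionally on the true $M$ (where 99% of null loci fall below
the prior's 95th percentile), checks posterior means against a
grid-integration oracle on a two-deme toy with fixed hyper-parameters
(agreement within 5%), and checks the ordering property (the selected
deme ranks first) with all hyper-parameters free. Deme sets that anchor
the migrant pool with a lowland majority — as the original deme design
did — sharpen the highland/lowland $\sigma$ contrast considerably.

`altitude_association()` regresses residence altitude (the quantitative
phenotype) on genotype per locus under additive ({0,1,2} dosage), dominant
(carrier indicator) and recessive (homozygote indicator) codings, the
standard trio of genetic models. The regression is individual-level by
default with a population-level weighted variant (`by_population = TRUE`),
since frequency-level phrasing admits either reading; the two agree
exactly on the covariance scale under within-population Hardy–Weinberg
structure. Monomorphic loci yield NA rows; degenerate perfect fits floor
the p-value at 10^-300^. Raw p-values are reported (as in the original
analysis), with a Bonferroni column for convenience.

## Forward simulation

`run_scenario()` tracks one locus through an ancestral population, a
split into lowland and highland daughters, and `round(split_years / 30)`
post-split Wright–Fisher generations (93, 333 and 1000 for splits of
2800, 10000 and 30000 years), with binomial resampling of $2N$
chromosomes around the deterministic selection update
$$p' = \frac{p^2 w_{AA} + p(1-p) w_{Aa}}{p^2 w_{AA} + 2p(1-p) w_{Aa} + (1-p)^2 w_{aa}}.$$
Selection acts only in the selected (highland) population after the
split. Strength is supplied as $\sigma$, with $s = \sigma / (2 N_e)$ of
the selected population, keeping $\sigma$ — the quantity actually
reported — invariant across size configurations. The published scenario
took its demographic parameters from the literature without printing
them; the package ships documented stand-ins: ancestral and lowland
$N_e = 10000$, highland $N_e = 1000$. The highland value follows the
small-isolate picture of a bottlenecked highland population and is the
regime in which $\sigma \approx 118$ drives a sweep on the observed
timescale: the deterministic recursion (logistic rate $s/2$ per
generation for additive fitness) then reaches ~0.99 from $p_0 = 0.1$ in
roughly $(2/s)\ln(0.99 \cdot 0.9 / (0.01 \cdot 0.1)) \approx 230$
generations, so the 1000-generation scenario fixes the allele in
essentially all replicates, while the 93-generation (2800-year) scenario
starting from $p_0 \in \{0.05, 0.1\}$ lands in the observed highland
frequency range (~0.6). Replicates run on derived seed substreams, so any
single replicate is reproducible in isolation. No recombination,
post-split migration or admixture is modelled.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages, writes every artifact with MD5
checksums into a JSON manifest (timestamps excluded from the
reproducibility contract), and can resume from cached per-stage state so
that deleting one stage's state re-runs only that stage. One master seed
propagates to every stochastic stage through fixed substream derivation.

Problem sizes used by the shipped validation and demo runs are the
package's own choices for a single-CPU desk run: synthetic surveys of
6–20 populations × 15–40 samples; phasing oracles on 6–8 samples × 4
loci with exhaustive enumeration; Steiner oracles on ≤ 6 haplotypes × 7
loci; MCMC chains of a few thousand sweeps with hundreds of retained
samples; 100 replicates per simulation grid cell. The underlying claims
(monotonicity, invariances, oracle agreement, orderings) are
size-independent; the sizes control only Monte-Carlo resolution.

## Known limitations

* The EM phaser ignores recombination and the coalescent prior; its
  haplotype list on real data would differ in rare haplotypes from
  PHASE-class tools (frequencies of common haplotypes agree).
* The island model treats demes as exchangeable migrant-pool members;
  hierarchical population structure is not modelled, and $M$/$\sigma$
  joint identification needs data at the original study's scale.
* The simulator's demographic stand-ins are documented defaults, not
  estimates; quantitative fixation claims are reproduced qualitatively
  under those stand-ins.
* Multistate or indel characters are out of scope throughout (binary
  ancestral/derived states only).
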