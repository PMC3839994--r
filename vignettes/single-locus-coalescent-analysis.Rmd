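---
title: "Single-locus haplotype analysis: models, estimators and design choices"
author: "xhaplo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-locus haplotype analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xhaplo)
```

## The problem

`xhaplo` analyses the variation of a single, effectively non-recombining
DNA segment typed as complete haplotypes with per-population counts.  The
motivating data set — bundled as `mtmr8_dataset()` — is an 11,024-bp
segment of the X-linked *MTMR8* gene typed in 160 chromosomes (111
sub-Saharan African, 49 non-African): 24 distinct haplotypes over 37
polymorphic positions, polarized against the chimpanzee.  Because male X
chromosomes are hemizygous, such data are directly phased, and because the
segment does not recombine, every statistic of interest can be computed
from a single genealogy.

The package covers the complete analysis chain: data model and formats,
outgroup polarization, perfect-phylogeny construction with CpG-recurrence
resolution, the classical diversity estimators and neutrality tests,
phylogenetically calibrated mutation dating (rho statistic), coalescent
maximum likelihood by Griffiths–Tavaré importance sampling, and an
infinite-sites coalescent simulator used both for null distributions and
for studying how demography moves the theta estimators.

## Data model and encodings

A `haplotype_dataset` stores sites (position, mutation label, ancestral
state, CpG flag), the haplotype-by-site allele matrix, per-population
counts, and outgroup/archaic allele rows.  Two encodings of the same data
play different roles:

* **Sequence view** (`as_binary_matrix()`): one 0/1 column per mutational
  *event group*.  Adjacent positions that always co-segregate and are
  interpreted as a single mutational event (the bundled table's `1-2`
  pair) collapse into one column, and recurrent mutations at one position
  are — as in the physical sequence — indistinguishable, hence one
  column.  All diversity statistics use this view; it is what
  sequence-based software sees.
* **Event view** (`resolve_recurrences()`): after the four-gamete check
  identifies conflicts at CpG-hypermutable sites, the conflicted columns
  are split into original plus starred copies (`25*`, `31*`), one per
  independent mutation.  The gene tree, and everything built on it
  (rho dating, coalescent likelihood), uses this view.

This distinction matters numerically.  Counting the `1-2` event once
reproduces the data set's published segregating-site counts (34 within
Africa, 36 overall) and all downstream statistics; counting its two
positions separately would inflate S, theta estimates and every
mutation-path length.

### Ancestral alleles

`infer_ancestral_alleles()` applies a fixed rule per site: a human allele
identical by state with the chimpanzee is ancestral; failing that,
agreement of at least two of the remaining outgroups with a human allele
decides; otherwise the site is flagged unresolved and excluded from
polarized statistics.  Archaic rows (Neandertal, Denisova) are
annotations only and never polarize.

### Recurrence resolution

`resolve_recurrences()` assumes the infinite-sites model holds except for
independent recurrences at CpG-flagged sites.  It searches, by
backtracking over the conflicted CpG columns and all bipartitions of each
column's carriers, for the minimal set of single-column duplications that
yields a perfect phylogeny; among equivalent splits the smaller carrier
subset receives the star.  Conflicts that cannot be attributed to a
CpG site raise an error rather than being resolved silently — a
deliberate design decision, since a non-CpG homoplasy in such data more
likely indicates recombination or a data problem, which the analyst must
judge.  On the bundled table the search reproduces the published
resolution exactly (haplotype H5 carries the recurrent `25*`, H2 the
recurrent `31*`).

## Gene tree

`build_gene_tree()` performs the standard Gusfield-style construction:
columns sorted by decreasing carrier count (ties by position), each
haplotype's sorted mutation list traced as a root path.  The root is the
all-ancestral state — rooting comes entirely from the outgroup
polarization, not from midpointing.  Mutations with identical carrier
sets share a branch; their within-branch order is stored by ascending
reference position and flagged *order-arbitrary*: nothing in the data
distinguishes which came first, and downstream reports carry the flag.

## Diversity statistics and neutrality tests

All estimators are computed per segment from the unfolded site frequency
spectrum (derived counts `c_j` at `n` chromosomes):

* theta_pi = sum 2 c (n−c) / (n(n−1)); theta_S = S / a_n with
  a_n = sum_{i<n} 1/i; theta_H = sum 2 c^2 / (n(n−1));
  theta_L = sum c / (n−1); theta_k solves E[K | theta, n] = k under the
  Ewens formula; theta_G = (1−F)/F with F the unbiased haplotype
  homozygosity.
* Gene diversity uses the unbiased n/(n−1) correction throughout.
* Tajima's D with Tajima's variance constants; p either by the
  bounded-beta approximation or by neutral coalescent simulation
  conditional on the observed S (lower tail).
* Fu's Fs from the exact Ewens probability
  S' = P(K ≥ k | theta = theta_pi), computed with unsigned Stirling
  numbers of the first kind in log space; the p-value simulates neutral
  samples at theta_pi and recomputes Fs per replicate.
* Fay & Wu's raw H is identically theta_pi − theta_H; the normalized
  statistic is (theta_pi − theta_L)/sqrt(Var) with the variance estimated
  from theta_S and S(S−1)/(a1^2+a2); p by fixed-S coalescent null.
* Ewens–Watterson and Slatkin tests sample haplotype configurations from
  the Ewens formula conditional on (n, k) via the Chinese-restaurant
  construction with rejection on K = k (at theta chosen so
  E[K] = k).  Watterson orders configurations by homozygosity, Slatkin
  by conditional configuration probability; both are validated against
  exhaustive partition enumeration in the test suite.
* Chakraborty's amalgamation quantity is E[K | theta_pi] together with
  the exact Ewens tail P(K ≥ k_obs).  Note that this tail probability is
  the same quantity as Fu's S'; published tables computed with legacy
  software sometimes print a different (undocumented) value for the
  amalgamation tail, which this package does not attempt to mimic.
* Phi-ST comes from the AMOVA variance decomposition of the pairwise
  difference matrix, computed on weighted haplotype counts without
  expanding chromosomes; negative among-population components are
  truncated at zero.

Missing data: sites with any missing entry are dropped listwise for
SFS-based statistics and handled pairwise (per-site complete counts) for
theta_pi; the bundled table has no missing entries.

## Mutation dating by the rho statistic

For a focal ancestral node, rho is the average number of mutations
between the node and its subtended sampled chromosomes, and
`sd(rho) = sqrt(sum_b (n_b/n)^2 m_b)` over branches below the node
(Saillard's estimator).  Age in generations is rho / mu with mu the
per-segment per-generation rate; years multiply by the generation time.

Conventions that the implementation fixes (and the tests pin against the
published data set):

* The focal point for *mutation* m sits immediately below m itself, so
  other mutations stored below m on the same branch count toward the
  descendant paths.  With the within-branch order fixed by ascending
  position ("the top mutation is the oldest"), this reproduces the
  published ages including the instructive case of a five-mutation
  branch, where dating the top mutation gives a far older age than
  dating the branch's child node would.
* The `1-2` event group counts as one mutation in all path lengths.

`calibrate_rate()` derives mu from interspecies divergence:
mu = divergence_per_bp × L × g / (2 T_split).  The default calibration
(0.0081 substitutions/bp against chimpanzee, 11,024 bp, 7.5 My split, 25
y/generation) gives 1.49e-4 per segment per generation (1.35e-8 /bp);
switching the split to 6 My raises the rate by 25% and scales every age
by 0.8.  The male/female rate ratio alpha converts X-linked to
autosomal-equivalent rates via 3(alpha+1)/(2(alpha+2)).  Saillard SDs are
reported plain by default; `rate_uncertainty = TRUE` adds a second SD
with the calibration's divergence uncertainty folded in, since published
tables are sometimes ambiguous about whether rate error was propagated.

## Griffiths–Tavaré importance sampling

The likelihood of the sample configuration, conditional on the rooted
gene tree, is estimated by simulating mutation/coalescence histories
backward.  Feasible events are coalescence of two identical lineages and
removal of a mutation carried by exactly one active lineage.  Event times
are proposed from the total intensity (all pairs at rate exp(beta t) per
pair — the exponential-growth model N(t) = N0 exp(−beta t) backward —
plus all lineages at rate theta/2); the weight multiplies by the feasible
fraction at each event.  Time is measured in units of 1.5 N0 generations
(X-linked scaling, theta = 3 N0 mu), so one unit is theta/(2 mu)
generations.

Two proposals are available: the classical backward-urn choice in
proportion to the true rates (`"gt"`), and a Stephens–Donnelly-style
refinement (`"sd"`, the default) that picks an actionable lineage
uniformly (coalescence weight n_v, removal weight 1).  On tiny trees both
match the exhaustive Ethier–Griffiths–Tavaré recursion exactly; on the
bundled 112-chromosome tree the refinement improves the effective sample
size by more than an order of magnitude and is the default.

Two further design choices matter for usable surfaces at realistic
budgets:

* **Surface from one driving run.** The log-density of a sampled history
  under any (theta, beta) differs from the driving values only through
  closed-form statistics of the history (number of mutations, lineage
  time integral, coalescence-time sum, and the pairwise-intensity
  integral on a beta grid), so one run evaluates the entire surface.
  The surface is smooth in the parameters and its argmax is far more
  stable than independent per-point runs at equal budget.
* **Staged profile search with a noise-based stop.** The growth model's
  (theta, beta) surface is a long flat diagonal ridge: parameter pairs
  from roughly (8, 0.6) to (11, 1.6) lie within well under one log unit
  of each other on the bundled tree, which is below the Monte-Carlo
  noise.  `profile_growth_search()` therefore reproduces the published
  staged procedure (explore beta at fixed theta, then theta at the
  selected beta, re-driving each round) and stops when a round no longer
  improves the likelihood beyond twice its Monte-Carlo SE.  Because the
  ridge is flat, theta and beta individually are weakly identified —
  while quantities like the TMRCA in years are much better determined,
  since higher theta (more generations per coalescent unit) compensates
  shorter coalescent times.

Posterior ages (`estimate_ages()`) are importance-weighted means and SDs
of event times at fixed (theta, beta), converted to generations via
theta/(2 mu).  Defaults: budget 1e6 histories for fixture-size
likelihood surfaces (the scale at which repeated runs with different
seeds agree), 3e5 per stage for the profile search.  The estimate of the
likelihood is unbiased only up to a constant factor independent of the
parameters (the usual order convention for mutations sharing a branch),
which cancels from ratios, maxima and posterior means.

## Coalescent simulator

`simulate_coalescent()` draws exact samples from the structured
coalescent: equal-sized demes with symmetric conservative migration
(`migration_4Nm` is 4Nm with N the present deme size; per-lineage rate
0.375 × 4Nm × d per unit), piecewise-exponential total size, and two
structural events — demes merging backward (`merge_time`: forward, a
population that split) and a panmictic sample population scattering
backward into demes (`scatter_time`: forward, demes that fused).
Mutations are Poisson with rate theta/2 per lineage per unit on the
realized genealogy (infinite sites).  Determinism: a fixed seed replays
byte-identical output.  The simulator is cross-checked against msprime
on growth and island scenarios in the test suite.

### Scenario presets and what they show

`coalsim_preset()` encodes the estimator-behaviour experiments.  Where
the motivating study did not state a quantity, the presets fix it once:
4 demes, equal sampling across demes, N0 = 20,000 for converting
generations (so 500 generations is 0.0167 units and 15,000 generations
0.5 units), and an ancestral reference of N = 4,000 for the five-fold
growth preset (t = 0.25 units, theta defined at the ancestral size — the
only reading under which "growth leaves theta_pi nearly unchanged while
doubling theta_S" is arithmetically possible).

The combined scenario deserves its own note.  The published experiment
"combining subdivision (4Nm = 2) with growth from 7,000 to 20,000 over
the last 15,000 generations" at input theta 7.5 yielded the ordering
theta_pi (5.39) < theta_S (6.33) < theta_ML (7.20).  Running subdivision
and growth *simultaneously* under this package's scaling does not
produce that ordering (subdivision's excess of intermediate-frequency
variants cancels the growth signal in theta_pi).  The source study's own
interpretation — "population subdivision and *subsequent* population
growth" — points to the sequential scenario: demes exchanging migrants
at 4Nm = 2 anciently, fusing 15,000 generations ago into a single
population that grows 7,000 → 20,000.  That realization produces the
published ordering cleanly and is the preset; its absolute means sit
10–15% below the published triple, within what the unstated simulation
conventions (deme count, time scaling, the N in 4Nm) can shift.  The
panmixia preset likewise: 4 isolated demes that fused 500 generations
ago leave essentially no trace, and all three estimators converge on the
input theta.

A related subtlety: the amalgamation (Chakraborty) test is *not*
enriched for small probabilities under equilibrium island-model
subdivision — there theta_pi is inflated so much that the expected
haplotype count exceeds the observed one.  The enrichment appears under
the data-like sequential scenario (structure pooled by fusion, then
growth), which is what `recovery_suite()` contrasts against panmixia.

## Synthetic data with ground truth

`generate_dataset()` dresses simulator output as a complete haplotype
table: random ancestral/derived bases at random positions, synthetic
outgroup rows (chimpanzee, orangutan, macaque) carrying the true
simulated ancestral allele with configurable error, per-deme population
counts, and optionally one injected CpG-style recurrent mutation with
recorded truth, so that the polarization rule, the four-gamete check and
the resolution search can be exercised end to end.  `(name, seed)`
determines the output byte-for-byte.

What the generator emulates: infinite-sites variation on a single
non-recombining genealogy under the supported demographies, with exact
outgroups.  What it does not: recombination and gene conversion,
selection, sequencing/phasing error, mutation-rate heterogeneity along
the segment (real CpG recurrence arises from rate heterogeneity; the
generator injects it structurally instead).  Tests passing on synthetic
data therefore validate the estimators and machinery under the model's
own assumptions, not robustness to their violation.

## Problem sizes and numerical choices

The test suite runs the full published-data checks at the package's
default budgets (1e6 driving histories for the constant-size surface,
3e5 per profile stage), simulation experiments at 120–500 replicates,
type-I-error checks at 2000 replicates with memoized fixed-S null
distributions, and enumeration oracles at n ≤ 9.  Tolerances follow the
source of the quantity: machine tolerance for identities, printed
precision for deterministic published values, Monte-Carlo bands
(typically 2–3 SE) for stochastic ones.  Ties in the conditional tests
are counted as "at least as extreme" with a 1e-12 slack; degenerate
inputs (monomorphic samples, zero rates, leaves as dating focus) return
flagged NA or zero results rather than errors wherever a downstream
report can represent them.

## Known limitations

* The likelihood machinery conditions on the gene tree and assumes
  panmixia within the likelihood model; no migration-aware likelihood.
* No recombination anywhere; the package is for loci chosen to be
  effectively non-recombining.
* The growth-model (theta, beta) pair is weakly identified on data of
  this size; report TMRCAs with their SDs rather than trusting point
  (theta, beta).
* Monte-Carlo p-values below ~1/replicates are reported as 0; raise
  `reps` where exact tail calibration matters.
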