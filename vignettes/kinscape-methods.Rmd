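---
title: "Methods: nested-scale analysis of genetic and social relatedness"
author: "kinscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested-scale analysis of genetic and social relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscape)
```

## The problem

Cooperative soil bacteria such as *Myxococcus xanthus* aggregate into
multicellular fruiting bodies when starved, and swarming colonies of
distinct genotypes often fail to merge when they meet (kin
discrimination). Whether an individual that disperses a short distance
lands among clonemates, compatible non-kin, or discriminating non-kin
depends on how relatedness is arranged in space at the scales dispersal
actually covers. `kinscape` analyses exactly that arrangement for a
hierarchically sampled population: clones within one fruiting body
(micrometres apart), fruiting bodies within one soil core (millimetres),
cores within a transect (centimetres), transects within a site (metres)
and sites within a landscape (kilometres).

Two relatedness criteria are carried through in parallel:

* **genetic identity** — two isolates share a multilocus sequence type
  (ST), i.e. their concatenated five-locus alignments are identical
  strings;
* **social identity** — two isolates belong to the same colony-merger
  allotype, i.e. no kin-discrimination (KD) phenotype appears at the
  interface of their swarming colonies relative to self–self controls.

## The spatial model

The design is categorical: a pair of isolates belongs to the scale of the
deepest hierarchical level at which their addresses differ
(`pair_scale()`). Each category is mapped to one representative metric
distance (`scale_distance()`). At the two smallest scales direct
measurement between cells is infeasible, so the representative distance
is one third of the relevant structure's diameter — fruiting bodies
(100 μm by default) and soil cores (0.9 cm) — giving 3.3e-05 m and
0.003 m. The centimetre (0.036 m), metre (18 m) and kilometre (11 000 m)
distances are field-measurement constants: they are averages over the
realized sampling layout and cannot be derived from the nominal 2-cm core
spacing and 10-m cluster spacing alone, so `scale_geometry()` treats them
as configuration with those defaults. Distances are reported to two
significant figures, matching the convention of the design; the exact
quotients are available with `digits = NULL`. Site labels are free-form
uppercase strings so that simulated landscapes are not restricted to
three sites.

## Genotypes, sequence types and diversity

Per-locus alignments (one FASTA per locus, record names = isolate names)
are concatenated in fixed locus order with gaps preserved
(`concatenate_loci()`); for the default five-locus panel the concatemer
is 1445 sites including gaps. ST assignment is exact string identity with
gaps and N as ordinary characters, because the haplotype is defined on
the gapped concatemer; labels follow order of first occurrence. Isolates
lacking any locus are excluded before analysis (the loader refuses them
unless `intersect_isolates = TRUE`).

Nucleotide diversity π is the mean proportion of differing sites over all
unordered pairs. Sites with a gap or N in either member of a pair are
dropped from that pair's comparison (pairwise deletion, the common
default of diversity estimators); complete deletion — dropping every
column containing any gap or N — is available by flag, since published
values computed under one mode need not reproduce exactly under the
other. Pairwise distances offer the p-distance (default), Jukes–Cantor
and Kimura two-parameter corrections via `ape::dist.dna`. The "maximum
composite likelihood" distance of MEGA is deliberately not offered: the
scale-resolved conclusions the package targets are qualitative over five
distance categories and insensitive to that choice, and every output
records the model actually used. A Jukes–Cantor distance is undefined at
p ≥ 0.75; the policy (`error`, the default, or an `Inf` sentinel) is
explicit.

## Independent pair resampling

Post hoc comparisons of identity across scales are biased if the same
isolate contributes to several pairwise comparisons. The sampler
(`sample_independent_pairs()`) therefore draws, per replicate and scale,
a fixed number of pairs under one global constraint: **no isolate appears
in more than one pair anywhere in the output**, across all replicates and
all scales (the default demand is 3 replicates × 4 pairs × 5 scales = 60
pairs over 120 distinct isolates). Construction is randomized greedy in
fixed scale order from micrometre (the scarcest resource — it needs two
clones of one fruiting body) to kilometre, restarting from scratch on a
dead end, up to `max_restarts` (1000); exhausting the restarts is an
error with a capacity report (`feasibility_report()` gives per-scale
maximum-matching upper bounds), never a silent relaxation. Draws are not
stratified by site; replicate membership is the order of construction.
All randomness flows from one recorded seed, and the sampler guarantees
validity and reproducibility, not uniformity over the space of all valid
pair sets.

## Kin-discrimination scoring

Each assayed pair carries an odd panel of binary observer scores (1 =
interface visibly altered relative to self–self controls). The adopted
call is the strict majority (`majority_call()`), with unanimity tracked
separately; an even panel is an error because a tie is undefined.
Self–self control rows must score majority 0 — the phenotype is defined
relative to those interfaces, so a discriminating control invalidates the
batch. Social identity is simply the complement of the majority call. The
rich qualitative interface phenotypes (boundary lines, altered fruiting
patterns) are collapsed to this single bit, which is also how such assays
are analysed in practice.

## Identity-decay curves and their comparison

`genetic_identity_curve()` / `social_identity_curve()` return per-scale,
per-replicate identity proportions plus the pooled proportion and
across-replicate standard deviation. The unit of analysis for
significance testing is the **replicate proportion** (e.g. 3 values per
scale), not the pair-level binary, because replicates — not pairs — are
the independent unit of the resampling design. `anova_tukey()` runs a
one-way ANOVA across scales followed by Tukey HSD contrasts
(`stats::TukeyHSD`, studentized-range quantiles computed numerically by
`stats::ptukey`; Tukey–Kramer automatically under unbalanced
replication). Proportions are not arcsine- or logit-transformed. When
every scale has zero within-scale variance but means differ, F is
undefined and the result carries an `exact_separation` flag instead of a
number.

`curve_correlation()` correlates the five pooled proportions of the
genetic and social curves (Pearson). With five points, significance is
delicate: the exhaustive permutation test over all 5! = 120 orderings is
offered (two-sided on |r|, resolution 1/120) alongside the parametric
t-test with 3 degrees of freedom. The two can disagree in the second
decimal; published correlation p-values of this kind typically come from
the t route, while the permutation route makes no distributional
assumption.

## Spatial-structure tests

* **Mantel test** (`mantel_test()`): Pearson correlation of the upper
  triangles, null by simultaneous row/column permutation (9999 by
  default), two-sided add-one estimator
  `p = (#{|r_perm| ≥ |r_obs|} + 1)/(n_perm + 1)`. A parametric t option
  exists for comparison only — it ignores the non-independence of
  pairwise distances, which is the reason the permutation test exists.
* **Mean-distance-by-scale curves** (`scale_distance_curve()`): the mean
  genetic distance over **all** qualifying pairs (not the independent
  subsample) per scale, overall or within one clade, with a least-squares
  polynomial (order 1 or 2) in log10 representative distance; scales with
  no qualifying pair are kept as NA and excluded from the fit.
* **Clade distribution tests**: `clade_absence_test()` is the lower-tail
  exact binomial probability of seeing at most the observed number of
  clade members at a site, at the clade's pooled frequency;
  `clade_frequency_test()` is the two-sided exact binomial test of a
  site's two-clade split against the pooled split.
* **Nearest-ST concordance** (`nearest_st_concordance()`): each ST is
  paired with its genetically nearest distinct ST (ties broken uniformly
  at random under the recorded seed, since no tie rule is canonical); the
  no-structure expectation is the analytic probability that two distinct
  random STs share a site given the site ST lists, with a
  label-permutation estimate reported alongside as a cross-check; the
  default alternative is "greater" because spatial structure inflates
  concordance.
* **Within- vs among-site distances** (`within_vs_among_site_test()`):
  equal numbers of within-site and among-site ST-pair distances for one
  clade, drawn without reusing any ST pair (the same no-reuse principle
  as the pair sampler), compared by a two-sided Wilcoxon rank-sum test
  (exact for small tie-free samples). Sampling ST pairs rather than
  isolate pairs avoids re-weighting by clonal abundance; this is a
  modelling choice and the isolate-pair alternative would weight common
  STs more heavily.

Clade assignments are consumed as input (or taken from simulator truth),
never inferred: phylogenetic tree estimation is out of the package's
scope.

## The landscape simulator

`simulate_landscape()` generates complete inputs with the statistical
structure the analysis assumes, so the whole pipeline can be exercised
and validated without any external data.

* **Genotype pool.** `n_clades` (3) founder haplotypes are made mutually
  equidistant by mutating disjoint site sets, at `clade_divergence`
  (0.08) — chosen so that a mixed sample has overall π on the few-percent
  scale typical of such multilocus panels. A pool of 12 lineages carries
  additional within-clade divergence (0.005).
* **Colonization.** Each site draws lineages from its own circulating
  pool of 4 (with a 0.1 chance per draw of a long-range migrant from the
  full pool). Each transect, core and fruiting body inherits its parent
  unit's resident lineage or, with the level's migration probability
  (0.45 / 0.35 / 0.25), recruits a fresh lineage circulating in the site
  — a "stay-or-escalate" draw rather than an explicit coalescent, because
  it reproduces the target pattern (identity decaying by level) with few,
  transparent parameters. Lineages acquire 2 private substitutions on
  first entering a site (making STs effectively site-private, as
  observed) and 1 per transect resident.
* **Fruiting bodies.** A fruiting body is single-founder with probability
  `founder_clonality` (0.82, the observed fraction of genetically
  homogeneous multi-isolate fruiting bodies); otherwise a second founder
  is recruited and clones split between the two, so heterogeneous bodies
  carry two haplotypes, matching the observation that polymorphic
  fruiting bodies harbour at most two STs.
* **Attrition.** The nominal 3^5 = 243-isolate design is thinned by
  fruiting-body missingness (0.28) and per-clone genotyping failure
  (0.15), giving ≈149 expected isolates — mirroring the realized
  attrition of such field designs (176 sampled → 147 genotyped). The
  defaults keep the default sampler demand (120 isolates) feasible.
* **Mutation and recombination.** Each clone adds Poisson(μL)
  substitutions (μ = 1e-5 per site, small enough that fruiting-body
  homogeneity is governed by founding, not mutation). Wherever n
  mutations are introduced, Poisson(0.26 · n) recombination tracts are
  also applied — the ρ/θ coupling — with geometric tract lengths of mean
  12 nt and donors restricted to lineages circulating in the same site,
  reflecting that recombination acts within local populations.
* **Kin discrimination** (`simulate_kd()`): the probability of a true KD
  phenotype is logistic in pairwise genetic distance,
  `plogis(-6 + 8000 d)` — near zero at d = 0 and saturating across
  within-clade distances. No quantitative dose–response is published for
  this assay; these coefficients are free defaults chosen once to give
  the qualitative shape (clonemates merge, within-core neighbours mixed,
  distant pairs discriminate), not estimates. Observer calls flip
  independently with ε = 0.02, the error rate implied by 3 disagreements
  in 150 triple-scored assays.

What the simulator does **not** emulate: coalescent genealogies,
selection, indel evolution (gap columns are fixed if configured at all),
linkage structure between loci, or any fitted correspondence to the
deposited sequences. Passing the simulator-based tests therefore shows
that the estimators recover the generating parameters of this
hierarchical model — not that real data satisfy the model.

One structural consequence worth noting: under full migration
("panmixia") the identity curve flattens across the millimetre-to-
kilometre scales, which migration governs, while the micrometre level is
governed by within-fruiting-body co-founding (`founder_clonality`) and
stays elevated. Tests of the panmictic limit therefore assert flatness
over the migration-governed scales.

## Numerical and degenerate-input policy

* All seeded operations restore the caller's RNG state; identical seeds
  give byte-identical outputs (files included, manifest timestamps
  aside).
* Saturated distance corrections: error by default, `Inf` on request.
* Zero-variance curves make correlations NA with a warning rather than
  an error, because a flat curve is a legitimate analysis outcome.
* Groups of size 1 in the diversity table report NA diversity but keep
  their counts; a pair with no comparable sites is an error naming the
  pair.
* Nearest-ST ties and multi-founder clone assignment are the only
  uniform-random tie-breaks, both under the recorded seed.

## Problem sizes used by the test suite

The suite validates statistical behaviour at sizes chosen to give tight
Monte-Carlo bounds while keeping a full run under a minute: brute-force
oracle comparisons at n ≤ 20 sequences and ≤ 12 isolates (where
exhaustive enumeration is feasible), Mantel size calibration over 1000
null simulations of 10 × 10 matrices with 99 permutations each, sampler
uniformity over 1000 draws of a 32-isolate symmetric design, and
simulator recovery over landscapes of ≈150 isolates. The pipeline default
of 9999 Mantel permutations is reduced in tests to keep them fast; the
estimator is identical.

## Known limitations

* The categorical distance model has no continuous geography; two
  isolates in different sites are always "one kilometre-scale unit"
  apart regardless of which sites.
* The sampler guarantees valid, reproducible pair sets but not maximum-
  entropy sampling over all valid sets; inclusion frequencies are only
  approximately uniform.
* ST identity is exact string equality: a single sequencing error
  creates a new ST. Upstream quality control is the user's
  responsibility.
* The ANOVA on 3 replicate proportions per scale has little power; it is
  faithful to the design it implements, not a recommendation for new
  designs.
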