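---
title: "Scoring, explaining and ranking non-coding regulatory variants with regvarRF"
author: "regvarRF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, explaining and ranking non-coding regulatory variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regvarRF)
```

## The problem

A whole-genome sequence yields millions of variants per individual, and
when no coding mutation explains a patient's phenotype, the causative
variant is often suspected to be regulatory: a single base change in an
enhancer, promoter or transcription-factor binding site that deregulates a
gene. Identifying such a variant means (i) scoring every candidate for
regulatory impact, (ii) understanding *why* a variant scores high, and
(iii) connecting it to the gene whose deregulation could cause the
disease. `regvarRF` implements this whole chain: matched negative-control
construction, balanced random-forest training, leakage-free evaluation,
additive per-variant score decomposition, contribution-profile
clustering, and disease-gene-filtered candidate ranking — all testable end
to end on synthetic data.

## The classifier and its training sets

Variants are represented as width-1 `GRanges` with `ref`, `alt`, `label`
and `variantType` columns, and annotated into a fixed-length numeric
vector by a `FeatureSchema`. The default schema has 41 features in four
categories: sequence (substitution type, CpG context), evolutionary
conservation (phyloP/phastCons-type scores, GERP score and elements, a
context-dependent tolerance score), functional genomics (counts of cell
types per 18-state chromatin model, median histone-mark fold changes,
TFBS and DNase overlaps) and enhancer–gene association overlaps. The
schema records, per feature, its data type, the rule used to aggregate
multiple overlapping track intervals (`max`, `or`, `value`, `count`,
`median`, or `computed` for features derived from the variant itself) and
its missing value. All missing values default to 0, which encodes "no
evidence" coherently across every feature family; random forests require
finite inputs, and imputation is recorded in the schema so it stays
auditable.

The central difficulty of this classification problem is the choice of
negative controls. Damaging regulatory variants in curated databases are
strongly biased toward gene-proximal biotypes (promoters, UTRs, introns),
while benign variants are everywhere. Three negative-control schemes are
implemented:

* **Random** — uniform draws from the benign pool. Easy to separate, but a
  model trained this way partly learns *location*, not function.
* **Local** — every benign variant within 1,000 bp of a positive. Hard
  local discrimination; positives with no neighbour in range are dropped
  and reported.
* **Adjusted** — negatives drawn only from cytogenetic bands containing at
  least one positive, with per-biotype quotas matched to the positives'
  biotype composition (largest-remainder rounding so quotas sum exactly;
  uniform sampling without replacement within strata; exhausted strata
  under-fill with a warning). This forces the model to learn functional
  differences rather than location bias.

Class imbalance is handled per tree: each of the `n_trees` trees (default
1000, depth ≤ 15, ≥ 1 sample per leaf, `floor(sqrt(p))` candidate features
per split) is grown on its own balanced multiset of exactly `n` draws with
replacement from each class, `n` being the smaller class size. The
per-tree multisets are recorded in the model object — they are the basis
of all out-of-bag computations later. A variant's score is the mean over
trees of the class-1 fraction of the leaf it reaches, a number in [0, 1]
interpretable as the proportion of trees voting "regulatory". Indels are
scored at every affected reference position (deleted bases for a deletion,
the anchor base for an insertion) plus one flank on each side, with both
substitution classes evaluated at each position; the maximum is reported
together with the full evaluation trace. Which substitution class an
indel "is" at a position is not observable, so taking the maximum over
both is recorded as an explicit convention.

## Leakage-free evaluation

Nearby variants share genomic context, and random cross-validation splits
let that context leak from training to validation folds, inflating
performance. `bandAwareFolds()` assigns whole cytogenetic bands to folds
(largest band first onto the smallest fold, ties shuffled by seed), so
same-band variants never straddle the split. Discrimination is summarised
by ROC and precision–recall curves; choices the underlying methods leave
open are fixed as follows and asserted in tests:

* ROC AUC by the trapezoidal rule over the full threshold sweep with tied
  scores crossing simultaneously — this equals the normalised Mann–Whitney
  U statistic, which the test suite uses as an independent oracle.
* PRC AUC by step interpolation (the average-precision form), avoiding
  the optimistic bias of linear interpolation.
* The decision threshold maximises F1 over the observed score values
  (smallest value among ties); the confusion matrix is reported at that
  threshold.
* Mean cross-validation curves are computed by vertical averaging on a
  fixed 101-point grid, with a 95% band of mean ± 1.96 sd across folds.
  This construction is a package choice, not claimed identical to any
  published figure's.

`crossSchemeEvaluate()` applies each scheme's per-fold models to the test
sets of the other schemes, excluding test variants that entered the fold
model's training rows and first subsampling negatives so positives form
12.5% of each test subset (`m = round(n_pos (1-f)/f)`), making curves
comparable across schemes with different class balances.

## Explaining scores

For interpretation the package provides two complementary views. *Feature
importance* (feature-centric) is the forest's mean decrease in Gini
impurity per feature, normalised to sum to one. *Feature contributions*
(variant-centric) decompose one variant's score additively: along each
tree's decision path, the change in node class-1 fraction between
consecutive nodes is credited to the feature the parent splits on; the
bias is the mean root fraction. By construction
`bias + sum(contributions) = score` over the same tree subset — the
package asserts this identity to 1e-9 on every computed vector, and the
test suite additionally checks equality with a brute-force path-
enumeration oracle on small forests. For training variants, contributions
are computed only over out-of-bag trees (trees whose balanced sample never
drew the variant), so explanations of training data are not overfit; with
balanced resampling of `n` from each class, the expected OOB fraction is
`(1 - 1/N_class)^n` (≈ `exp(-1)` ≈ 0.37 for the smaller class), which the
tests verify.

Functional profiles pair each variant's raw feature values — rescaled to
[-1, 1] by their signed quantile position in a background reference
distribution (median → 0, extremes → ±1; a quantile map is used rather
than min–max for robustness to heavy-tailed conservation scores) — with
the signed contributions, and `plotFunctionalProfile()` renders them.

Positive-variant contribution matrices are clustered with k-means
(`selectKAndCluster()`): K from 2 to 19, ten seeded restarts per K, best
inertia kept, and the silhouette-maximising K selected. When silhouette
and the inertia elbow disagree, silhouette decides — a deterministic rule
is required — and the full inertia curve is returned for inspection.
Clusters are characterised against everything outside them (other
positives plus negatives) by per-feature effect sizes: Cohen's d for
continuous and discrete features, Cohen's h
(`2(asin(sqrt(pA)) - asin(sqrt(pB)))`, on the proportion of non-zero
values) for binary ones. A zero pooled standard deviation with unequal
means yields signed infinity, reported rather than thrown.

## Ranking candidates by disease genes

Regulatory-region→target-gene resources are merged by unioning
overlapping intervals (a shared base pair suffices; adjacency does not
merge) into maximal regions carrying the union of target genes and
evidence sources; designated resources can be passed through unmerged.
`filterByDiseaseGenes()` keeps scored variants overlapping at least one
region whose targets intersect the disease-gene set and ranks them by
score, ties broken by ascending coordinate and alternate allele so ranks
are reproducible. `spikeInBenchmark()` emulates the clinical setting:
known pathogenic variants are seeded into a benign background, everything
is restricted to annotated regulatory regions, scored, filtered by the
disease's genes and ranked; spike-ins falling in no region targeting
their gene are flagged unrankable rather than silently ranked — the
realistic failure mode of target-gene-based filtering.

## The synthetic-data generator

All tests and the acceptance script run on data from
`simulationConfig()` / `simulateLayout()` / `simulateVariants()`. The
generator emulates the *structure* of the real inputs, not their content:

* 2 contigs × 10 Mb, tiled by 20 cytogenetic bands each;
* 200 genes (promoter 2 kb upstream of the TSS, UTRs, three CDS exons,
  introns with 2 bp splice sites), placed one per slot;
* 500 enhancer-like regions within 50 kb of TSSs targeting their nearest
  genes, plus promoter/UTR segments as regions targeting their own gene —
  together the region–gene map the ranking workflow consumes;
* 800 positive variants drawn inside promoter/UTR/intron segments in
  clumps of 1–3 a few hundred bp apart (curated damaging mutations
  cluster), versus a 50,000-variant benign pool, 40% of which is drawn
  from gene-proximal segments (`poolGeneBias`) — clinical benign databases
  are strongly gene-biased by ascertainment, and without this the
  biotype-matched sampler would exhaust its gene-proximal strata;
* feature values drawn class-conditionally: five informative continuous
  (conservation-type) features shifted by Cohen's d = 3 in positives by
  default, binary features with configurable per-class rates, Poisson
  counts for the chromatin-state features, and the substitution-type
  feature computed from the simulated alleles;
* spatial autocorrelation: a fraction `autocorWeight` (default 0.5) of
  each continuous feature's noise variance is shared by all variants in
  the same 2 kb window, the minimal mechanism that makes random-split
  cross-validation optimistic relative to band-aware cross-validation.

`simulateTracks()` materialises the simulated matrix as per-feature 1 bp
interval tracks; annotating the variants with those tracks through the
ordinary annotation path reproduces the matrix exactly, tying the
generator to the real pipeline. `writeFixtures()`/`readFixtures()` write
and read everything in the pipeline's external formats (VCF, BED, TSV,
JSON).

What passing tests on these data do and do not show: they validate the
*mechanics* — sampling contracts, decomposition identities, fold
assignment, ranking logic, recovery of known signal at the configured
effect sizes — under Gaussian/Bernoulli feature marginals and a simple
window-noise covariance. They say nothing about performance on real
epigenomic annotations, whose marginals are heavy-tailed and whose
correlations are richer than shared window noise.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale problem sizes chosen to exercise
every code path in a few minutes on one CPU: the default study (800
positives, 50k pool, adjusted n_total 8,000) with 300-tree forests for
cross-validation; the leakage comparison at effect size 0.5 and
autocorrelation weight 0.7 with Random-scheme negatives, where the effect
has room to express itself (at d = 3 both schemes saturate near AUC 1, and
biotype-matched negatives share windows with positives, neutralising
window identity — so those conditions cannot display the phenomenon); and
the spike-in benchmark with 30 held-out positives seeded among a 10k
benign background. Tree counts are hyperparameters, not study conditions:
300 trees already yield AUC ≈ 1.0 at the default effect size and identical
contracts; the package default remains 1000.

Other numerical conventions: contig names are matched after stripping any
`chr` prefix and preserved on output; BED input is converted to the
1-based closed convention internally (a query at a BED interval's start
coordinate misses it, one past the start hits); multi-allelic VCF records
are split per alternate allele and scored independently; all floats are
written with 6 significant digits; every stochastic function takes an
integer seed and restores the caller's RNG state, so a single master seed
makes a whole run bit-reproducible.

## Known limitations

* The default schema's category counts (3/7/25/6) are a reconstruction:
  the authoritative published feature list is not redistributable, so the
  schema is configurable and the shipped default mirrors the documented
  feature families.
* Gini-importance is biased toward high-cardinality features; with the
  mixed binary/discrete/continuous schema this mildly favours continuous
  features. The contribution decomposition does not share this bias.
* The generator does not simulate sequence content (beyond alleles),
  realistic conservation-score marginals, or assembly liftover; structural
  variants and genome-wide precomputation are out of scope.
* K-means on contribution vectors assumes roughly spherical clusters in
  contribution space; silhouette-based selection can prefer coarse
  clusterings when clusters are elongated.
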