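# regvarRF

Random-forest scoring, interpretation and ranking of non-coding
regulatory variants.

When whole-genome sequencing finds no coding mutation for a diagnosed
disease, the causative variant is often regulatory — a single base change
in an enhancer, promoter or transcription-factor binding site. `regvarRF`
is an R package for prioritising such variants. It covers the full
analysis chain:

* **Matched negative controls.** Three sampling schemes for benign
  controls: *Random* (uniform), *Local* (within 1,000 bp of a known
  damaging variant) and *Adjusted* (restricted to cytogenetic bands
  containing damaging variants, with the negatives' biotype composition —
  promoter/UTR/intron/intergenic — matched to the positives'), so the
  classifier learns function rather than genomic location.
* **Balanced random forest.** Each tree is grown on its own balanced
  resample of *n* draws with replacement per class (*n* = smaller class
  size). A variant's score is the proportion of trees classifying it as
  regulatory: the mean over trees of the class-1 fraction of the leaf it
  reaches, in [0, 1]. Indels are scored at every affected position plus
  one flank each side, for both substitution classes; the maximum is
  reported.
* **Leakage-free evaluation.** Cross-validation folds are assigned at the
  cytogenetic-band level, so nearby variants never straddle the
  train/validation split; ROC/PRC curves, the F1-optimal threshold and
  cross-scheme comparison grids come with it.
* **Interpretable scores.** Each score decomposes exactly as
  `score = bias + Σ_f contribution_f` along the forest's decision paths,
  computed out-of-bag for training variants. Contribution profiles of
  damaging variants can be clustered (k-means, silhouette-selected K) and
  clusters characterised by Cohen's d / Cohen's h effect sizes.
* **Disease-gene ranking.** Regulatory-region→target-gene resources are
  merged into maximal regions; candidate variants are filtered to regions
  targeting the disease's genes and ranked by score — with a spike-in
  benchmark that seeds known pathogenic variants into a benign background
  and measures their rank.
* **Synthetic data.** A generator builds a complete miniature study —
  genome layout, bands, genes, region–gene maps, annotation tracks, and
  two variant classes at configurable effect sizes with spatially
  autocorrelated features — so the entire pipeline is testable offline.

## Worked example

```r
library(regvarRF)

## a synthetic study: 300 damaging variants vs a 10k benign pool
cfg    <- simulationConfig(nPositives = 300L, nNegativePool = 10000L, seed = 7L)
layout <- simulateLayout(cfg)
sim    <- simulateVariants(cfg, layout)
pos    <- sim$variants[sim$variants$label == "positive"]
pool   <- sim$variants[sim$variants$label == "negative"]

## adjusted negative controls: positive-bearing bands, biotypes matched
adj <- sampleAdjusted(pool, pos, layout$bands, layout$genes,
                      n_total = 3000L, seed = 1L)
adj$report
#> SamplingReport [adjusted]: 3000 of 3000 requested

vars  <- c(pos, adj$variants)
X     <- sim$X[match(variantKey(vars), variantKey(sim$variants)), ]  # or annotateVariants()
model <- trainForest(X, vars$label, defaultFeatureSchema(),
                     forestParams(n_trees = 300L, seed = 2L))
model
#> RegForestModel: 300 trees, 41 features, 3300 training rows
#>   classes: negative / positive  threshold: 0.5
#>   params: max_depth = 15 , min_samples_leaf = 1 , mtry = 6

## band-aware 10-fold cross-validation
fa <- bandAwareFolds(vars, layout$bands, k = 10L, seed = 3L)
cv <- crossValidate(X, vars$label, fa$fold_of_variant,
                    defaultFeatureSchema(), forestParams(n_trees = 300L, seed = 4L))
cv
#> EvalReport over 10 fold(s): ROC AUC 1 / PRC AUC 1
#>   F1-optimal threshold: 0.56 (F1 = 1 )

## the five informative features dominate the importance ranking
head(sort(featureImportance(model), decreasing = TRUE), 5)
#>     phyloP_vertebrates             GERP_score  phastCons_vertebrates
#>              0.2219540              0.1996234              0.1873580
#>                   CDTS TFBS_cluster_max_score
#>              0.1850649              0.1469751

## out-of-bag additive score decomposition: bias + contributions = score
ct <- featureContributions(model, X, trainingIds = seq_len(nrow(X)))
ct
#> ContributionSet: 3300 variants, 41 features;  3300 OOB-restricted
summary(ct$bias + rowSums(ct$contributions) - ct$score)
#>       Min.    1st Qu.     Median       Mean    3rd Qu.       Max.
#> -3.261e-16 -9.975e-17 -5.204e-17 -4.959e-17  0.000e+00  2.637e-16
```

Here the cross-validated ROC AUC of 1.0 reflects the generator's default
class separation (five informative features shifted by d = 3); the
importance ranking recovers exactly those five features, and the
contribution identity holds to machine precision. Downstream,
`mergeRegulatoryDatasets()`, `filterByDiseaseGenes()` and
`spikeInBenchmark()` turn the scores into per-disease candidate rankings.

A thin command-line wrapper over the same functions ships in
`inst/scripts/regvar-cli.R` (subcommands `simulate`, `sample-controls`,
`train`, `score`, `contributions`, `evaluate`, `rank`).

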