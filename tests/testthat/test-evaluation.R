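test_that("band-aware folds partition variants and never split a band", {
  st <- sharedStudy()
  vars <- st$sim$variants
  fa <- bandAwareFolds(vars, st$layout$bands, k = 10L, seed = 3L)
  expect_length(fa$fold_of_variant, length(vars))
  expect_setequal(unique(fa$fold_of_variant), 1:10)
  ## leakage contract: same band -> same fold, checked over all pairs via
  ## the band -> fold map
  hits <- GenomicRanges::findOverlaps(vars, st$layout$bands)
  bandOf <- S4Vectors::subjectHits(hits)
  expect_true(all(tapply(fa$fold_of_variant, bandOf,
                         function(f) length(unique(f))) == 1L))
  ## two variants 100 bp apart share a fold, always
  v2 <- makeVariants("chr1", c(1000100L, 1000200L), "A", "G")
  fa2 <- bandAwareFolds(v2, st$layout$bands, k = 10L, seed = 1L)
  expect_equal(fa2$fold_of_variant[1], fa2$fold_of_variant[2])
  expect_error(bandAwareFolds(v2, st$layout$bands[1], k = 2L),
               "exceeds the number of bands")
})

test_that("ten equal bands with k = 10 give one band per fold", {
  bands <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, 10000, 1000), width = 1000))
  bands$band_name <- paste0("q", 1:10)
  v <- makeVariants("chr1", seq(500, 9500, 1000), "A", "G")
  fa <- bandAwareFolds(v, bands, k = 10L, seed = 1L)
  expect_setequal(fa$fold_of_band, 1:10)
  expect_equal(anyDuplicated(fa$fold_of_band), 0L)
})

test_that("ROC AUC equals the normalised Mann-Whitney U statistic", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    labels <- sample(c("positive", "negative"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    u <- wilcox.test(scores[labels == "positive"],
                     scores[labels == "negative"],
                     exact = FALSE)$statistic
    expect_equal(rocAuc(scores, labels),
                 unname(u) / (sum(labels == "positive") *
                                sum(labels == "negative")),
                 tolerance = 1e-12)
  }
})

test_that("curves behave at the extremes", {
  expect_equal(rocAuc(c(0.9, 0.1), c("positive", "negative")), 1.0)
  expect_equal(prcAuc(c(0.9, 0.1), c("positive", "negative")), 1.0)
  expect_equal(rocAuc(c(0.1, 0.9), c("positive", "negative")), 0.0)
  ## chance level for label-independent scores
  set.seed(8)
  s <- runif(4000)
  l <- rep(c("positive", "negative"), 2000)
  expect_equal(rocAuc(s, l), 0.5, tolerance = 0.03)
  expect_error(rocAuc(runif(5), rep("positive", 5)), "both classes")
})

test_that("the F1-optimal threshold follows the sweep contract", {
  ## separable: the smallest maximising observed value is the positive score
  r <- optimalThresholdF1(c(0.2, 0.8), c("negative", "positive"))
  expect_equal(r$threshold, 0.8)
  expect_equal(r$f1, 1.0)
  r2 <- optimalThresholdF1(c(1, 1, 0, 0),
                           c("positive", "positive", "negative", "negative"))
  expect_equal(r2$f1, 1.0)
  ## anti-correlated scores: best achievable F1 is the all-positive baseline
  sc <- c(0.9, 0.8, 0.2, 0.1)
  lb <- c("negative", "negative", "positive", "positive")
  r3 <- optimalThresholdF1(sc, lb)
  prev <- 0.5
  expect_equal(r3$f1, 2 * prev / (1 + prev))  # recall 1, precision = prev
  ## exhaustive-sweep oracle on random data
  set.seed(33)
  for (rep in 1:10) {
    s <- round(runif(40), 2)
    l <- sample(c("positive", "negative"), 40, replace = TRUE)
    if (length(unique(l)) < 2) next
    f1At <- vapply(sort(unique(s)), function(t) {
      tp <- sum(s >= t & l == "positive")
      fp <- sum(s >= t & l == "negative")
      fn <- sum(s < t & l == "positive")
      if (tp == 0) return(0)
      p <- tp / (tp + fp); rc <- tp / (tp + fn)
      2 * p * rc / (p + rc)
    }, numeric(1))
    r <- optimalThresholdF1(s, l)
    expect_equal(r$f1, max(f1At), tolerance = 1e-12)
    expect_equal(r$threshold,
                 min(sort(unique(s))[f1At >= max(f1At) - 1e-12]))
  }
})

test_that("confusion matrices count every evaluated variant once", {
  s <- c(0.9, 0.6, 0.4, 0.2)
  l <- c("positive", "negative", "positive", "negative")
  cm <- confusionAtThreshold(s, l, 0.5)
  expect_equal(sum(cm), 4)
  expect_equal(cm["positive", "positive"], 1)
  expect_equal(cm["negative", "positive"], 1)
})

test_that("negative subsampling hits the target positive fraction", {
  expect_length(subsampleToPositiveFraction(1:10000, 877L, 0.125, 1L), 6139L)
  expect_length(subsampleToPositiveFraction(1:100, 10L, 0.5, 1L), 10L)
  expect_length(subsampleToPositiveFraction(1:100, 1L, 0.125, 1L), 7L)
  expect_warning(kept <- subsampleToPositiveFraction(1:5, 100L, 0.125, 1L),
                 "too small")
  expect_length(kept, 5L)
})

test_that("cross-validation reports fold curves and the mean band", {
  td <- tinyData(n = 300L, p = 4L, shift = 2.5, seed = 6L)
  fold <- stratifiedFolds(td$y, k = 5L, seed = 1L)
  cv <- crossValidate(td$X, td$y, fold, tinySchema(4L),
                      forestParams(n_trees = 60L, seed = 4L))
  expect_equal(nrow(cv$per_fold), 5L)
  expect_gt(cv$roc_auc, 0.85)
  expect_equal(nrow(cv$mean_roc), 101L)
  expect_true(all(cv$mean_roc$lower <= cv$mean_roc$upper))
  expect_equal(sum(cv$confusion), 300)
})

test_that("the cross-scheme grid reproduces own-CV on the diagonal and
          degrades off-diagonal for the local scheme", {
  st <- sharedStudy()
  pos <- st$sim$variants[st$sim$variants$label == "positive"]
  pool <- st$sim$variants[st$sim$variants$label == "negative"]
  key <- variantKeyOf(st$sim$variants)
  Xof <- function(v) st$sim$X[match(variantKeyOf(v), key), , drop = FALSE]
  rnd <- sampleRandom(pool, 400L, seed = 2L)$variants
  loc <- sampleLocal(pool, pos, window_bp = 1000L)$variants
  negSets <- list(
    random = list(variants = rnd, X = Xof(rnd)),
    local = list(variants = loc, X = Xof(loc)))
  ## (warnings about small per-fold local negative pools are expected at
  ## this test scale)
  grid <- suppressWarnings(
    crossSchemeEvaluate(pos, Xof(pos), negSets, st$layout$bands,
                        defaultFeatureSchema(),
                        forestParams(n_trees = 60L, seed = 3L),
                        seed = 14L))
  ## diagonal = own cross-validation (recomputed independently)
  expect_s3_class(grid$random$random, "EvalReport")
  allv <- c(GenomicRanges::granges(pos), GenomicRanges::granges(rnd))
  fa <- bandAwareFolds(allv, st$layout$bands, k = 10L, seed = 3L)
  ownCv <- crossValidate(rbind(Xof(pos), Xof(rnd)),
                         rep(c("positive", "negative"),
                             c(length(pos), length(rnd))),
                         fa$fold_of_variant, defaultFeatureSchema(),
                         forestParams(n_trees = 60L, seed = 3L))
  expect_equal(grid$random$random$roc_auc, ownCv$roc_auc,
               tolerance = 1e-12)
  ## the random model evaluated on local negatives does no better than on
  ## its own easy negatives
  expect_lte(grid$random$local$roc_auc, grid$random$random$roc_auc + 0.02)
})

test_that("method comparison drops variants missing any score", {
  tbl <- data.frame(a = c(0.9, 0.8, NA, 0.4),
                    b = c(0.7, 0.1, 0.5, 0.9))
  lb <- c("positive", "negative", "positive", "negative")
  cmp <- compareMethodScores(tbl, lb)
  expect_equal(cmp$n_used, 3L)
  expect_equal(cmp$n_dropped, 1L)
  expect_setequal(cmp$aucs$method, c("a", "b"))
})
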