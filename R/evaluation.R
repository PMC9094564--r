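#' @include model.R
NULL

asBinaryLabels <- function(labels) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L) stop("both classes must be present")
  lv <- levels(f)
  if ("positive" %in% lv) lv <- c(setdiff(lv, "positive"), "positive")
  as.integer(factor(as.character(f), levels = lv)) - 1L
}

#' Cytogenetic-band-aware k-fold assignment
#'
#' Variants located close together share genomic context, so splitting
#' them across training and validation folds leaks information and
#' inflates apparent performance.  Band-aware folds prevent this: whole
#' cytogenetic bands are assigned to folds (largest band first onto the
#' currently smallest fold, ties shuffled by seed), and every variant
#' inherits its band's fold — two variants in the same band can never
#' straddle the train/validation split.
#'
#' @param variants variant `GRanges`; each variant must lie in exactly one
#'   band.
#' @param bands band `GRanges` (non-overlapping).
#' @param k number of folds (default 10); must not exceed the number of
#'   bands.
#' @param seed integer seed for tie shuffling.
#' @return list with `fold_of_variant` (integer per variant),
#'   `fold_of_band` (integer per band), `k`, `seed`.
#' @export
bandAwareFolds <- function(variants, bands, k = 10L, seed = 1L) {
  if (k > length(bands))
    stop("k = ", k, " exceeds the number of bands (", length(bands), ")")
  hits <- GenomicRanges::findOverlaps(variants, bands)
  if (length(unique(S4Vectors::queryHits(hits))) != length(variants))
    stop("every variant must lie in exactly one band")
  bandOf <- integer(length(variants))
  bandOf[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  counts <- tabulate(bandOf, nbins = length(bands))
  ord <- withSeed(seed, order(counts + runif(length(counts)),
                              decreasing = TRUE))
  foldOfBand <- integer(length(bands))
  load <- numeric(k)
  for (b in ord) {
    f <- which.min(load)
    foldOfBand[b] <- f
    load[f] <- load[f] + counts[b]
  }
  list(fold_of_variant = foldOfBand[bandOf], fold_of_band = foldOfBand,
       k = as.integer(k), seed = as.integer(seed))
}

#' Stratified random k-fold assignment
#'
#' Random fold assignment stratified by class label only: positions are
#' ignored, so nearby variants may straddle folds.  Used as the
#' leakage-prone baseline against [bandAwareFolds()].
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments.
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = 1L) {
  fold <- integer(length(labels))
  withSeed(seed, for (cl in unique(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  })
  fold
}

## Tie-aware sweep over score thresholds: one row per distinct score,
## cumulative TP/FP counting all variants with score >= that value.
scoreSweep <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yy <- y[o]
  tp <- cumsum(yy)
  fp <- cumsum(1 - yy)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  list(threshold = s[last], tp = tp[last], fp = fp[last],
       nPos = sum(y), nNeg = sum(1 - y))
}

#' ROC curve and area under it
#'
#' True-positive rate as a function of false-positive rate over the full
#' threshold sweep, tied scores crossing simultaneously; the area is
#' computed by the trapezoidal rule and equals the normalised
#' Mann-Whitney U statistic of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels two-class labels (level `positive`, or the second factor
#'   level, is the positive class).
#' @return `rocCurve`: `data.frame` with columns `fpr`, `tpr` (including
#'   the (0,0) and (1,1) endpoints); `rocAuc`: the area, in [0, 1].
#' @export
rocCurve <- function(scores, labels) {
  y <- asBinaryLabels(labels)
  sw <- scoreSweep(scores, y)
  data.frame(fpr = c(0, sw$fp / sw$nNeg), tpr = c(0, sw$tp / sw$nPos))
}

#' @rdname rocCurve
#' @export
rocAuc <- function(scores, labels) {
  pts <- rocCurve(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' Precision-recall curve and area under it
#'
#' Precision as a function of recall over the threshold sweep.  The area
#' uses step-wise interpolation (the average-precision form
#' `sum (R_i - R_{i-1}) P_i`), which avoids the optimistic bias of linear
#' interpolation between precision-recall points.
#'
#' @inheritParams rocCurve
#' @return `prcCurve`: `data.frame` with columns `recall`, `precision`;
#'   `prcAuc`: the area, in [0, 1].
#' @export
prcCurve <- function(scores, labels) {
  y <- asBinaryLabels(labels)
  sw <- scoreSweep(scores, y)
  data.frame(recall = sw$tp / sw$nPos,
             precision = sw$tp / (sw$tp + sw$fp))
}

#' @rdname prcCurve
#' @export
prcAuc <- function(scores, labels) {
  pts <- prcCurve(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' F1-optimal decision threshold
#'
#' Sweeps the observed score values as candidate thresholds (predicting
#' positive when `score >= threshold`) and returns the one maximising the
#' F1 score, the harmonic mean of precision and recall; among tied
#' thresholds the smallest is returned.
#'
#' @inheritParams rocCurve
#' @return list with `threshold` and `f1`.
#' @export
optimalThresholdF1 <- function(scores, labels) {
  y <- asBinaryLabels(labels)
  sw <- scoreSweep(scores, y)
  precision <- sw$tp / pmax(sw$tp + sw$fp, 1L)
  recall <- sw$tp / sw$nPos
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  best <- f1 >= max(f1) - 1e-12
  thr <- min(sw$threshold[best])
  list(threshold = thr, f1 = max(f1))
}

#' Confusion matrix at a threshold
#'
#' @inheritParams rocCurve
#' @param threshold score threshold; `score >= threshold` predicts
#'   positive.
#' @return 2x2 integer matrix (rows = truth, columns = prediction).
#' @export
confusionAtThreshold <- function(scores, labels, threshold) {
  y <- asBinaryLabels(labels)
  pred <- as.integer(scores >= threshold)
  m <- table(factor(y, levels = 0:1), factor(pred, levels = 0:1))
  dimnames(m) <- list(truth = c("negative", "positive"),
                      predicted = c("negative", "positive"))
  m
}

#' Subsample negatives to a target positive fraction
#'
#' Keeps `m = round(n_pos * (1 - f) / f)` negatives so that positives make
#' up fraction `f` of the combined set (within one variant).  Used to
#' renormalise test sets when comparing evaluation schemes whose class
#' balances differ.
#'
#' @param negatives vector, `GRanges` or indices of negative items.
#' @param n_pos number of positives the set will be combined with.
#' @param target_fraction desired positive fraction (default 0.125).
#' @param seed integer seed.
#' @return subset of `negatives` (a warning is issued and all are kept if
#'   too few are available).
#' @export
subsampleToPositiveFraction <- function(negatives, n_pos,
                                        target_fraction = 0.125, seed = 1L) {
  m <- round(n_pos * (1 - target_fraction) / target_fraction)
  n <- if (inherits(negatives, "GRanges")) length(negatives)
       else length(negatives)
  if (m >= n) {
    if (m > n) warning("negative pool too small: kept all ", n)
    return(negatives)
  }
  idx <- withSeed(seed, sort(sample.int(n, m)))
  negatives[idx]
}

## Vertical averaging of per-fold curves on a fixed grid of 101 x-values;
## the band is mean +/- 1.96 sd across folds.
meanCurve <- function(curves, xcol, ycol) {
  grid <- seq(0, 1, length.out = 101L)
  ys <- vapply(curves, function(cv)
    stats::approx(cv[[xcol]], cv[[ycol]], xout = grid, rule = 2,
                  ties = max)$y,
    numeric(101L))
  mu <- rowMeans(ys)
  sdv <- apply(ys, 1L, sd)
  data.frame(x = grid, mean = mu,
             lower = pmax(0, mu - 1.96 * sdv),
             upper = pmin(1, mu + 1.96 * sdv))
}

evalReport <- function(scores, labels, fold) {
  folds <- sort(unique(fold))
  perFold <- do.call(rbind, lapply(folds, function(f) {
    s <- scores[fold == f]; l <- labels[fold == f]
    data.frame(fold = f, roc_auc = rocAuc(s, l), prc_auc = prcAuc(s, l))
  }))
  rocCurves <- lapply(folds, function(f)
    rocCurve(scores[fold == f], labels[fold == f]))
  prcCurves <- lapply(folds, function(f)
    prcCurve(scores[fold == f], labels[fold == f]))
  opt <- optimalThresholdF1(scores, labels)
  structure(list(
    per_fold = perFold,
    roc_auc = mean(perFold$roc_auc),
    prc_auc = mean(perFold$prc_auc),
    roc_points = rocCurve(scores, labels),
    prc_points = prcCurve(scores, labels),
    mean_roc = meanCurve(rocCurves, "fpr", "tpr"),
    mean_prc = meanCurve(prcCurves, "recall", "precision"),
    optimal_threshold = opt$threshold, f1 = opt$f1,
    confusion = confusionAtThreshold(scores, labels, opt$threshold),
    scores = scores, labels = labels, fold = fold),
    class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport over", nrow(x$per_fold), "fold(s):",
      "ROC AUC", round(x$roc_auc, 3),
      "/ PRC AUC", round(x$prc_auc, 3), "\n")
  cat("  F1-optimal threshold:", round(x$optimal_threshold, 3),
      "(F1 =", round(x$f1, 3), ")\n")
  invisible(x)
}

#' Cross-validated evaluation of the balanced forest
#'
#' Trains one forest per fold on the remaining folds and scores the held
#' out fold, then summarises discrimination with per-fold and mean ROC and
#' precision-recall curves, the F1-optimal threshold on the pooled
#' out-of-fold scores, and the confusion matrix at that threshold.
#'
#' @param X feature matrix.
#' @param y labels.
#' @param fold integer fold assignment per row (from [bandAwareFolds()] or
#'   [stratifiedFolds()]).
#' @param schema the [FeatureSchema-class].
#' @param params hyperparameters from [forestParams()]; each fold model is
#'   trained with a distinct seed derived from `params$seed`.
#' @param keep_models keep the per-fold models in the report (needed by
#'   [crossSchemeEvaluate()]).
#' @return an `EvalReport` (list; see [print.EvalReport()]), with the
#'   pooled out-of-fold `scores` and, when requested, `models`.
#' @export
crossValidate <- function(X, y, fold, schema, params = forestParams(),
                          keep_models = FALSE) {
  Xm <- asFeatureMatrix(X, schema)
  folds <- sort(unique(fold))
  if (length(folds) < 2L) stop("at least two folds required")
  scores <- numeric(nrow(Xm))
  seeds <- childSeeds(params$seed, length(folds))
  models <- if (keep_models) vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[i]
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("fold ", f, ": training split lost a class")
    p <- params
    p$seed <- seeds[i]
    m <- trainForest(Xm[tr, , drop = FALSE], y[tr], schema, p)
    scores[!tr] <- scoreMatrix(m, Xm[!tr, , drop = FALSE])
    if (keep_models) models[[i]] <- stripEngine(m)
  }
  rep <- evalReport(scores, y, fold)
  if (keep_models) {
    rep$models <- models
    rep$fold_ids <- folds
  }
  rep
}

#' Cross-scheme evaluation grid
#'
#' Applies the fold models of each negative-sampling scheme to the test
#' sets of every scheme, quantifying how well each model generalises to
#' negatives drawn differently from its own training set.  For cell
#' (model m, dataset d), the per-fold models from m's cross-validation are
#' re-used: fold f is evaluated on the shared positives of fold f plus
#' dataset d's negatives lying in fold-f bands, excluding any test variant
#' that entered that fold model's training rows, with d's negatives first
#' subsampled so positives make up `target_fraction` of each test subset.
#' Diagonal cells reproduce each scheme's own cross-validation.
#'
#' @param positives positive variant `GRanges` (shared across schemes).
#' @param posX feature matrix of the positives.
#' @param negSets named list (one per scheme) of lists with elements
#'   `variants` (negative `GRanges`) and `X` (their feature matrix).
#' @param bands band `GRanges`.
#' @param schema the [FeatureSchema-class].
#' @param params hyperparameters from [forestParams()].
#' @param target_fraction positive fraction test sets are renormalised to
#'   (default 0.125).
#' @param seed integer seed.
#' @return matrix-like named list of lists: `result[[model]][[dataset]]`
#'   is an `EvalReport`.
#' @export
crossSchemeEvaluate <- function(positives, posX, negSets, bands, schema,
                                params = forestParams(),
                                target_fraction = 0.125, seed = 1L) {
  schemes <- names(negSets)
  stopifnot(!is.null(schemes), all(nzchar(schemes)))
  posKey <- variantKey(positives)
  seeds <- childSeeds(seed, length(schemes)^2 * 12L)
  si <- 0L
  out <- stats::setNames(vector("list", length(schemes)), schemes)
  for (m in schemes) {
    negm <- negSets[[m]]
    allVar <- c(GenomicRanges::granges(positives),
                GenomicRanges::granges(negm$variants))
    Xall <- rbind(posX, negm$X)
    yall <- rep(c("positive", "negative"),
                c(length(positives), length(negm$variants)))
    keys <- c(posKey, variantKey(negm$variants))
    fa <- bandAwareFolds(allVar, bands, k = min(10L, length(bands)),
                         seed = params$seed)
    cv <- crossValidate(Xall, yall, fa$fold_of_variant, schema, params,
                        keep_models = TRUE)
    out[[m]] <- stats::setNames(vector("list", length(schemes)), schemes)
    for (d in schemes) {
      if (d == m) {
        out[[m]][[d]] <- cv
        next
      }
      negd <- negSets[[d]]
      negFold <- bandFoldOf(negd$variants, bands, fa$fold_of_band)
      posFold <- fa$fold_of_variant[seq_along(positives)]
      sc <- numeric(0); lb <- character(0); fl <- integer(0)
      for (i in seq_along(cv$fold_ids)) {
        f <- cv$fold_ids[i]
        mod <- cv$models[[i]]
        trainKeys <- keys[fa$fold_of_variant != f]
        pi <- which(posFold == f)
        ni <- which(negFold == f &
                      !(variantKey(negd$variants) %in% trainKeys))
        si <- si + 1L
        ni <- subsampleToPositiveFraction(ni, length(pi), target_fraction,
                                          seed = seeds[si])
        if (!length(pi) || !length(ni)) next
        Xtest <- rbind(posX[pi, , drop = FALSE],
                       negd$X[ni, , drop = FALSE])
        sc <- c(sc, scoreMatrix(mod, Xtest))
        lb <- c(lb, rep(c("positive", "negative"),
                        c(length(pi), length(ni))))
        fl <- c(fl, rep(f, length(pi) + length(ni)))
      }
      out[[m]][[d]] <- evalReport(sc, lb, fl)
    }
  }
  out
}

bandFoldOf <- function(variants, bands, fold_of_band) {
  hits <- GenomicRanges::findOverlaps(variants, bands)
  fold <- rep(NA_integer_, length(variants))
  fold[S4Vectors::queryHits(hits)] <-
    fold_of_band[S4Vectors::subjectHits(hits)]
  fold
}

#' Compare externally supplied method scores
#'
#' Joins score columns from other variant-scoring methods with the labels
#' and reports ROC/PRC AUC per method.  Variants missing a score for any
#' method are excluded for all methods (the common drop-out rule), so all
#' methods are compared on the identical variant set.
#'
#' @param scoreTable `data.frame` of score columns, one per method; NA
#'   marks a missing score.
#' @param labels class labels, one per row.
#' @return list with `aucs` (`data.frame`: method, roc_auc, prc_auc),
#'   `n_used`, `n_dropped`.
#' @export
compareMethodScores <- function(scoreTable, labels) {
  keep <- stats::complete.cases(scoreTable)
  st <- scoreTable[keep, , drop = FALSE]
  lb <- labels[keep]
  aucs <- do.call(rbind, lapply(names(st), function(mth)
    data.frame(method = mth, roc_auc = rocAuc(st[[mth]], lb),
               prc_auc = prcAuc(st[[mth]], lb))))
  list(aucs = aucs, n_used = sum(keep), n_dropped = sum(!keep))
}
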