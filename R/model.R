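#' @include AllClasses.R sampling.R
NULL

#' Forest hyperparameters
#'
#' Defaults follow the tuned configuration used throughout the package:
#' 1000 trees, maximum depth 15, minimum of one sample per leaf, and
#' `floor(sqrt(p))` candidate features per split (the canonical
#' classification default; configurable via `mtry`).
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param min_samples_leaf minimum samples per leaf.
#' @param mtry features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param seed integer seed controlling both the per-tree balanced
#'   resampling and tree growing.
#' @return a named list of parameters.
#' @export
forestParams <- function(n_trees = 1000L, max_depth = 15L,
                         min_samples_leaf = 1L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L, min_samples_leaf >= 1L)
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       min_samples_leaf = as.integer(min_samples_leaf),
       mtry = if (!is.null(mtry)) as.integer(mtry), seed = as.integer(seed))
}

## Convert one ranger tree into flat 1-based arrays.
extractTree <- function(rf, t) {
  ti <- ranger::treeInfo(rf, t)
  ti <- ti[order(ti$nodeID), ]
  list(left = as.integer(ti$leftChild + 1L),
       right = as.integer(ti$rightChild + 1L),
       var = as.integer(ti$splitvarID + 1L),
       split = as.numeric(ti$splitval),
       terminal = ti$terminal,
       value = rep(NA_real_, nrow(ti)))
}

## Class-1 fraction of the tree's balanced inbag sample at every node,
## obtained by routing the inbag multiset down the tree level by level.
computeNodeValues <- function(tree, Xm, w, y1) {
  nn <- length(tree$left)
  sw <- numeric(nn)
  swy <- numeric(nn)
  rows <- which(w > 0)
  cur <- rep(1L, length(rows))
  repeat {
    s <- rowsum(cbind(w[rows], w[rows] * y1[rows]), cur)
    ids <- as.integer(rownames(s))
    sw[ids] <- sw[ids] + s[, 1L]
    swy[ids] <- swy[ids] + s[, 2L]
    keep <- !tree$terminal[cur]
    if (!any(keep)) break
    rows <- rows[keep]
    cur <- cur[keep]
    goleft <- Xm[cbind(rows, tree$var[cur])] <= tree$split[cur]
    cur <- ifelse(goleft, tree$left[cur], tree$right[cur])
  }
  tree$value <- ifelse(sw > 0, swy / sw, NA_real_)
  tree
}

## Coerce a feature matrix/data.frame to the numeric matrix the forest
## expects, checking it against the schema.
asFeatureMatrix <- function(X, schema) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix or data.frame")
  if (ncol(X) != nFeatures(schema))
    stop("X has ", ncol(X), " columns but schema has ", nFeatures(schema),
         " features")
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), featureNames(schema)))
    stop("X column names do not match schema feature order")
  if (anyNA(X)) stop("X contains NA; impute missing values first")
  colnames(X) <- featureNames(schema)
  X
}

#' Train a balanced random forest on annotated variants
#'
#' Each of the `n_trees` trees is grown on its own balanced multiset of
#' training rows (exactly `n` draws with replacement per class, `n` the
#' smaller class size; see [balancedTreeSamples()]), split by Gini impurity
#' decrease over `mtry` randomly drawn candidate features per node.  The
#' per-tree samples and the class-1 fraction of each tree's sample at every
#' node are retained: they are what make out-of-bag score and contribution
#' computation possible later.
#'
#' @param X feature matrix (rows = variants, columns = schema features).
#' @param y labels: factor or character with classes `negative` /
#'   `positive` (any two-level labelling works; the second level, or the
#'   level named "positive", is the class scored).
#' @param schema the [FeatureSchema-class] describing `X`'s columns.
#' @param params hyperparameters from [forestParams()].
#' @return a [RegForestModel-class].  A constant (zero-variance) feature
#'   matrix still trains, with a warning that all importances are zero.
#' @examples
#' X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
#' X[1:50, 1] <- X[1:50, 1] + 3
#' sch <- FeatureSchema(data.frame(
#'   name = c("a", "b"), group = "conservation", dtype = "continuous",
#'   aggregation = "value", missing_value = 0))
#' y <- rep(c("positive", "negative"), each = 50)
#' m <- trainForest(X, y, sch, forestParams(n_trees = 20, seed = 1))
#' @export
trainForest <- function(X, y, schema, params = forestParams()) {
  Xm <- asFeatureMatrix(X, schema)
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2L) stop("two classes required")
  lv <- levels(y)
  if ("positive" %in% lv) lv <- c(setdiff(lv, "positive"), "positive")
  y <- factor(as.character(y), levels = lv)
  y1 <- as.integer(y == lv[2L])

  samples <- balancedTreeSamples(y, params$n_trees, params$seed)
  inbag <- lapply(samples, tabulate, nbins = nrow(Xm))
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(Xm))))

  df <- as.data.frame(Xm)
  rf <- ranger::ranger(x = df, y = y, num.trees = params$n_trees,
                       mtry = mtry, min.node.size = params$min_samples_leaf,
                       max.depth = params$max_depth, probability = TRUE,
                       inbag = inbag, importance = "impurity",
                       seed = params$seed, num.threads = 1L)

  trees <- lapply(seq_len(params$n_trees), function(t)
    computeNodeValues(extractTree(rf, t), Xm, inbag[[t]], y1))

  imp <- rf$variable.importance
  if (sum(imp) <= 0)
    warning("all split importances are zero (constant feature matrix?)")
  params$mtry <- mtry
  params$importance <- imp

  methods::new("RegForestModel", trees = trees,
               inbag = lapply(inbag, as.integer),
               schema = schema, params = params, threshold = 0.5,
               classLevels = lv, nTraining = nrow(Xm), engine = rf)
}

#' Drop the internal prediction engine from a model
#'
#' Removes the fitted ranger object, leaving the explicit tree structures.
#' All package functionality remains available (scoring falls back to the
#' package's own path routing); the object becomes smaller and fully
#' self-described.
#'
#' @param model a [RegForestModel-class].
#' @return the model without its engine.
#' @export
stripEngine <- function(model) {
  model@engine <- NULL
  model
}

## Route rows of Xm through the trees in `treeIdx`, accumulating leaf
## values and (optionally) per-feature decision-path contributions.
## `eligible`, if given, is a logical matrix [row x tree]; row/tree pairs
## marked FALSE do not contribute.
routeForest <- function(model, Xm, treeIdx = NULL, contrib = FALSE,
                        eligible = NULL) {
  M <- nrow(Xm)
  p <- ncol(Xm)
  treeIdx <- treeIdx %||% seq_along(model@trees)
  leafSum <- numeric(M)
  biasSum <- numeric(M)
  nUsed <- integer(M)
  CM <- if (contrib) matrix(0, M, p,
                            dimnames = list(NULL, colnames(Xm)))
  for (t in treeIdx) {
    tr <- model@trees[[t]]
    rows <- if (is.null(eligible)) seq_len(M) else which(eligible[, t])
    if (!length(rows)) next
    cur <- rep(1L, length(rows))
    repeat {
      int <- which(!tr$terminal[cur])
      if (!length(int)) break
      r <- rows[int]
      v <- tr$var[cur[int]]
      goleft <- Xm[cbind(r, v)] <= tr$split[cur[int]]
      nxt <- ifelse(goleft, tr$left[cur[int]], tr$right[cur[int]])
      if (contrib) {
        delta <- tr$value[nxt] - tr$value[cur[int]]
        CM[cbind(r, v)] <- CM[cbind(r, v)] + delta
      }
      cur[int] <- nxt
    }
    leafSum[rows] <- leafSum[rows] + tr$value[cur]
    biasSum[rows] <- biasSum[rows] + tr$value[1L]
    nUsed[rows] <- nUsed[rows] + 1L
  }
  list(leafSum = leafSum, biasSum = biasSum, nUsed = nUsed, contrib = CM)
}

#' Score feature vectors with a trained forest
#'
#' The score of a variant is the proportion of trees classifying it as
#' regulatory, computed as the mean over trees of the class-1 fraction of
#' the leaf the variant reaches (a soft vote; with one sample per leaf,
#' leaves are near-pure and this equals the fraction of trees voting
#' class 1).  Scores always lie in [0, 1].
#'
#' @param model a [RegForestModel-class].
#' @param X feature matrix matching the model schema.
#' @param trees optional integer vector restricting the ensemble to a tree
#'   subset (the score is then the mean over that subset).
#' @param useEngine use the internal engine for batch prediction when
#'   available and no tree subset is requested (identical results, faster).
#' @return numeric vector of scores in [0, 1].
#' @export
scoreMatrix <- function(model, X, trees = NULL, useEngine = TRUE) {
  Xm <- asFeatureMatrix(X, model@schema)
  if (is.null(trees) && useEngine && !is.null(model@engine)) {
    pr <- stats::predict(model@engine, data = as.data.frame(Xm),
                         num.threads = 1L)$predictions
    return(as.numeric(pr[, model@classLevels[2L]]))
  }
  rt <- routeForest(model, Xm, treeIdx = trees)
  rt$leafSum / pmax(rt$nUsed, 1L)
}

#' Score variants (SNVs and indels) from annotation tracks
#'
#' SNVs are annotated at their position and scored directly.  Indels are
#' scored by [scoreIndel()]: every affected reference position plus one
#' flanking position on each side is evaluated for both substitution
#' classes, and the maximum score is reported.
#'
#' @param model a [RegForestModel-class].
#' @param variants variant `GRanges`.
#' @param tracks named list of [IntervalTrack-class] (see
#'   [annotateVariants()]).
#' @return `data.frame` with contig, pos, ref, alt, score, and the
#'   predicted class at the model's decision threshold.
#' @export
scoreVariants <- function(model, variants, tracks) {
  sch <- model@schema
  score <- numeric(length(variants))
  isIndel <- variants$variantType == "indel"
  if (any(!isIndel)) {
    X <- annotateVariants(variants[!isIndel], tracks, sch)
    score[!isIndel] <- scoreMatrix(model, X)
  }
  for (i in which(isIndel))
    score[i] <- scoreIndel(model, variants[i], tracks)$score
  data.frame(contig = as.character(GenomeInfoDb::seqnames(variants)),
             pos = GenomicRanges::start(variants),
             ref = variants$ref, alt = variants$alt, score = score,
             predicted = ifelse(score >= model@threshold,
                                model@classLevels[2L], model@classLevels[1L]))
}

#' Score an indel by evaluating all affected positions
#'
#' A deletion affects its deleted reference bases, an insertion its anchor
#' base; one flanking position on each side is evaluated as well.  At every
#' evaluated position two predictions are made — one with the substitution
#' type set to transition and one to transversion — and the maximum over
#' all (position, class) pairs is reported, with the full evaluation trace.
#'
#' @param model a [RegForestModel-class].
#' @param indel a single-variant `GRanges` with `variantType == "indel"`.
#' @param tracks named list of [IntervalTrack-class].
#' @return list with `variant`, `score` (the maximum), and
#'   `evaluated_positions` (`data.frame` of position, substitution class
#'   and score; `score == max(evaluated_positions$score)` always).
#' @export
scoreIndel <- function(model, indel, tracks) {
  stopifnot(length(indel) == 1L)
  if (indel$variantType != "indel") stop("variant is not an indel")
  p <- GenomicRanges::start(indel)
  d <- nchar(indel$ref) - nchar(indel$alt)
  positions <- if (d > 0) seq(p, p + d + 1L) else seq(p - 1L, p + 1L)
  positions <- positions[positions >= 1L]
  if (!length(positions)) stop("indel has no evaluable position on contig")
  contig <- as.character(GenomeInfoDb::seqnames(indel))
  probe <- makeVariants(rep(contig, length(positions)), positions,
                        rep("A", length(positions)),
                        rep("G", length(positions)))
  X <- annotateVariants(probe, tracks, model@schema)
  vtCol <- match("variant_type", featureNames(model@schema))
  classes <- c(transition = 1, transversion = 2)
  ev <- do.call(rbind, lapply(names(classes), function(cl) {
    Xc <- X
    if (!is.na(vtCol)) Xc[, vtCol] <- classes[[cl]]
    data.frame(position = positions, substitution_class = cl,
               score = scoreMatrix(model, Xc))
  }))
  ev <- ev[order(ev$position, ev$substitution_class), ]
  rownames(ev) <- NULL
  list(variant = indel, score = max(ev$score), evaluated_positions = ev)
}

#' Precompute per-position scores over an interval
#'
#' Evaluates every reference position of an interval for both substitution
#' classes, emitting the two-prediction-per-position table used for fast
#' lookup of precomputed scores (intended for toy-scale intervals; the
#' output is an ordinary sorted TSV-ready table).
#'
#' @param model a [RegForestModel-class].
#' @param contig contig name.
#' @param start,end 1-based closed interval of positions to evaluate.
#' @param tracks named list of [IntervalTrack-class].
#' @return `data.frame` with columns `contig`, `pos`, `score_transition`,
#'   `score_transversion`.
#' @export
precomputeScores <- function(model, contig, start, end, tracks) {
  stopifnot(start >= 1L, end >= start)
  positions <- seq.int(start, end)
  probe <- makeVariants(rep(contig, length(positions)), positions,
                        "A", "G")
  X <- annotateVariants(probe, tracks, model@schema)
  vtCol <- match("variant_type", featureNames(model@schema))
  scoreAs <- function(code) {
    Xc <- X
    if (!is.na(vtCol)) Xc[, vtCol] <- code
    scoreMatrix(model, Xc)
  }
  data.frame(contig = contig, pos = positions,
             score_transition = scoreAs(1),
             score_transversion = scoreAs(2))
}

#' Feature importance of a trained forest
#'
#' Mean decrease in Gini impurity attributable to each feature, averaged
#' over all nodes and trees where the feature was used for splitting,
#' normalised to sum to one.  This is the feature-centric companion of the
#' variant-centric [featureContributions()].
#'
#' @param model a [RegForestModel-class].
#' @return named numeric vector over features, summing to 1.
#' @export
featureImportance <- function(model) {
  imp <- model@params$importance
  s <- sum(imp)
  if (s <= 0) return(stats::setNames(rep(0, length(imp)), names(imp)))
  imp / s
}

#' Save / load a trained model
#'
#' The model is written as a single versioned archive holding the trees,
#' the feature schema, the per-tree sample records, the decision threshold
#' and the hyperparameters.
#'
#' @param model a [RegForestModel-class].
#' @param path file path.
#' @param keep_engine keep the internal prediction engine in the archive
#'   (larger file, faster batch scoring on reload).
#' @return `saveModel` the path invisibly; `readModel` the model.
#' @export
saveModel <- function(model, path, keep_engine = FALSE) {
  if (!keep_engine) model <- stripEngine(model)
  obj <- list(format = "regvarRF-model", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
readModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "regvarRF-model"))
    stop("not a regvarRF model archive: ", path)
  validObject(obj$model)
  obj$model
}
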