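#' @include model.R
NULL

#' Additive per-feature contributions to variant scores
#'
#' Decomposes each variant's score into a bias term (the mean root-node
#' class-1 fraction over the trees used) plus one additive contribution per
#' feature.  For each tree the variant's decision path is walked from the
#' root; the change in the node class-1 fraction between consecutive nodes
#' is credited to the feature the parent node splits on.  Summed along the
#' path and averaged over trees this yields the exact identity
#' `bias + sum(contributions) = score` (over the same tree subset), which
#' is asserted to 1e-9 on every computed vector.
#'
#' When `trainingIds` are supplied (for variants that were part of the
#' training set), only out-of-bag trees — trees whose balanced sample did
#' not draw that variant — are used, so that contributions of training
#' variants are not overfit.  A variant drawn into every tree falls back to
#' all trees with `oob = FALSE` and a warning.
#'
#' @param model a [RegForestModel-class].
#' @param X feature matrix matching the model schema.
#' @param trainingIds optional integer vector (one per row of `X`, NA for
#'   rows that were not training variants): the training-row index of each
#'   variant, used to determine out-of-bag trees.
#' @return an object of class `ContributionSet`: a list with `bias`,
#'   `contributions` (matrix, rows = variants, columns = features),
#'   `score` (over the trees used), `nTreesUsed`, and `oob` (logical per
#'   variant).
#' @examples
#' X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
#' X[1:20, 1] <- X[1:20, 1] + 3
#' sch <- FeatureSchema(data.frame(
#'   name = c("a", "b"), group = "conservation", dtype = "continuous",
#'   aggregation = "value", missing_value = 0))
#' y <- rep(c("positive", "negative"), each = 20)
#' m <- trainForest(X, y, sch, forestParams(n_trees = 10, seed = 1))
#' ct <- featureContributions(m, X, trainingIds = seq_len(40))
#' all.equal(ct$bias + rowSums(ct$contributions), ct$score)
#' @export
featureContributions <- function(model, X, trainingIds = NULL) {
  Xm <- asFeatureMatrix(X, model@schema)
  M <- nrow(Xm)
  Tn <- length(model@trees)
  oob <- rep(FALSE, M)
  eligible <- NULL
  if (!is.null(trainingIds)) {
    stopifnot(length(trainingIds) == M)
    inbagMat <- do.call(cbind, model@inbag)
    eligible <- matrix(TRUE, M, Tn)
    has <- !is.na(trainingIds)
    eligible[has, ] <- inbagMat[trainingIds[has], , drop = FALSE] == 0L
    oob[has] <- TRUE
    none <- rowSums(eligible) == 0L
    if (any(none)) {
      warning(sum(none), " variant(s) present in every tree's sample; ",
              "falling back to all trees for them")
      eligible[none, ] <- TRUE
      oob[none] <- FALSE
    }
  }
  rt <- routeForest(model, Xm, contrib = TRUE, eligible = eligible)
  n <- pmax(rt$nUsed, 1L)
  out <- list(bias = rt$biasSum / n,
              contributions = rt$contrib / n,
              score = rt$leafSum / n,
              nTreesUsed = rt$nUsed,
              oob = oob)
  resid <- abs(out$bias + rowSums(out$contributions) - out$score)
  if (any(resid > 1e-9))
    stop("internal error: contribution decomposition off by ",
         max(resid))
  class(out) <- "ContributionSet"
  out
}

#' @export
print.ContributionSet <- function(x, ...) {
  cat("ContributionSet:", length(x$score), "variants,",
      ncol(x$contributions), "features; ",
      sum(x$oob), "OOB-restricted\n")
  invisible(x)
}

#' Write a contribution set as TSV
#'
#' One row per variant: bias, one column per feature contribution, number
#' of trees used, and the OOB flag.
#'
#' @param ct a `ContributionSet` from [featureContributions()].
#' @param path output path.
#' @param variants optional variant `GRanges` providing key columns.
#' @param comment optional header comment.
#' @return the path, invisibly.
#' @export
writeContributionsTsv <- function(ct, path, variants = NULL,
                                  comment = NULL) {
  df <- data.frame(bias = ct$bias, check.names = FALSE)
  df <- cbind(df, as.data.frame(ct$contributions, check.names = FALSE))
  df$n_trees_used <- ct$nTreesUsed
  df$oob <- ct$oob
  if (!is.null(variants))
    df <- cbind(data.frame(
      contig = as.character(GenomeInfoDb::seqnames(variants)),
      pos = GenomicRanges::start(variants),
      ref = variants$ref, alt = variants$alt), df)
  writeTsv(df, path, comment)
}

#' Reference distribution for functional-profile rescaling
#'
#' Stores, per feature, the sorted background values (typically raw
#' feature values over the annotated regulatory-region background) used to
#' map raw values onto [-1, 1].
#'
#' @param X background feature matrix (columns named by feature).
#' @return an object of class `ReferenceDistribution`.
#' @export
referenceDistribution <- function(X) {
  ref <- lapply(seq_len(ncol(X)), function(j) sort(X[, j]))
  names(ref) <- colnames(X)
  structure(ref, class = "ReferenceDistribution")
}

#' Functional profile of one variant
#'
#' Pairs the variant's raw feature values, rescaled to [-1, 1] by their
#' signed quantile position in a background reference distribution (the
#' reference median maps to 0, the minimum to -1, the maximum to +1), with
#' the signed per-feature contributions that explain its score.  The
#' quantile map is used rather than min-max scaling for robustness to
#' heavy-tailed features such as conservation scores.
#'
#' @param x named numeric vector: the variant's raw feature values.
#' @param cv one row of a `ContributionSet` (list with `bias`,
#'   `contributions` vector), or NULL to omit contributions.
#' @param reference a `ReferenceDistribution`.
#' @return list with `rescaled_values` (in [-1, 1]) and `contributions`.
#' @export
functionalProfile <- function(x, cv, reference) {
  stopifnot(inherits(reference, "ReferenceDistribution"))
  resc <- vapply(names(x), function(fn) {
    r <- reference[[fn]]
    if (is.null(r)) {
      warning("feature absent from reference distribution: ", fn)
      return(0)
    }
    if (length(r) == 1L || r[1] == r[length(r)])
      return(0)
    F <- stats::approx(x = r, y = seq(0, 1, length.out = length(r)),
                       xout = x[[fn]], rule = 2, ties = mean)$y
    2 * F - 1
  }, numeric(1))
  list(rescaled_values = resc, contributions = cv)
}

#' Plot a functional profile
#'
#' Bar heights are the rescaled raw feature values in [-1, 1]; bar colours
#' encode the sign and magnitude of the per-feature contributions (red
#' positive, blue negative).
#'
#' @param profile output of [functionalProfile()].
#' @param ... passed to `barplot`.
#' @return the bar midpoints, invisibly.
#' @export
plotFunctionalProfile <- function(profile, ...) {
  v <- profile$rescaled_values
  contr <- profile$contributions$contributions
  if (is.matrix(contr)) contr <- contr[1L, ]
  col <- "grey70"
  if (!is.null(contr)) {
    m <- max(abs(contr), 1e-12)
    shade <- pmin(1, abs(contr) / m)
    col <- ifelse(contr >= 0,
                  grDevices::rgb(1, 1 - shade, 1 - shade),
                  grDevices::rgb(1 - shade, 1 - shade, 1))
  }
  graphics::barplot(v, col = col, border = NA, las = 2,
                    cex.names = 0.55, ylim = c(-1, 1),
                    ylab = "rescaled feature value", ...)
}
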