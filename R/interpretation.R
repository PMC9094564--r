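#' @include explain.R
NULL

#' K-means clustering of contribution profiles with K selection
#'
#' Runs k-means (multiple seeded restarts, best inertia kept) on a matrix
#' of per-variant feature contributions for each K in `k_range`, and
#' returns the model at the silhouette-maximising K.  Inertia
#' (within-cluster sum of squares) is reported across K for elbow
#' inspection; when silhouette and inertia point to different K, the
#' silhouette decides — a deterministic rule is required and mean
#' silhouette width is the sharper criterion of the two.
#'
#' @param contributions numeric matrix (rows = variants, columns =
#'   features), typically `$contributions` of a `ContributionSet`.
#' @param k_range integer vector of length 2: smallest and largest K
#'   explored (default 2 to 19).
#' @param seed integer seed.
#' @param nstart k-means restarts per K (default 10).
#' @return object of class `ClusterModel`: list with `k`, `centroids`,
#'   `assignment`, `inertia`, `silhouette`, `by_k` (`data.frame` of K,
#'   silhouette, inertia), `seed`.
#' @export
selectKAndCluster <- function(contributions, k_range = c(2L, 19L),
                              seed = 1L, nstart = 10L) {
  M <- as.matrix(contributions)
  if (nrow(unique(M)) < 2L)
    stop("degenerate input: all contribution rows are identical")
  ks <- seq(max(2L, k_range[1]), k_range[2])
  if (nrow(M) < max(ks) + 1L)
    stop("need at least k_max + 1 rows")
  d <- stats::dist(M)
  fits <- vector("list", length(ks))
  sil <- numeric(length(ks))
  inertia <- numeric(length(ks))
  seeds <- childSeeds(seed, length(ks))
  for (i in seq_along(ks)) {
    fit <- withSeed(seeds[i],
                    stats::kmeans(M, centers = ks[i], nstart = nstart,
                                  iter.max = 100L))
    fits[[i]] <- fit
    inertia[i] <- fit$tot.withinss
    sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)
  fit <- fits[[best]]
  structure(list(k = ks[best], centroids = fit$centers,
                 assignment = fit$cluster, inertia = inertia[best],
                 silhouette = sil[best],
                 by_k = data.frame(k = ks, silhouette = sil,
                                   inertia = inertia),
                 seed = as.integer(seed)),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat("ClusterModel: k =", x$k, "(silhouette", round(x$silhouette, 3),
      "), sizes:", paste(table(x$assignment), collapse = "/"), "\n")
  invisible(x)
}

#' Cohen's d: standardised mean difference
#'
#' `(mean(A) - mean(B)) / sd_pooled` with the pooled standard deviation
#' `sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))`.  A zero pooled
#' standard deviation with unequal means yields signed `Inf` (reported,
#' not thrown); with equal means, 0.
#'
#' @param groupA,groupB numeric vectors with at least 2 values each.
#' @return a single number (possibly `Inf`/`-Inf`).
#' @examples
#' cohensD(c(0, 2), c(1, 3))  # -1/sqrt(2)
#' @export
cohensD <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 2L, nB >= 2L)
  num <- mean(groupA) - mean(groupB)
  sp <- sqrt(((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) /
               (nA + nB - 2))
  if (sp == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sp
}

#' Cohen's h: effect size for a difference of proportions
#'
#' The arcsine-square-root form `2 (asin(sqrt(pA)) - asin(sqrt(pB)))`.
#'
#' @param pA,pB proportions in [0, 1].
#' @return a single number in [-pi, pi].
#' @examples
#' cohensH(1, 0)        # pi
#' cohensH(0.5, 0.25)   # pi/6
#' @export
cohensH <- function(pA, pB) {
  if (any(c(pA, pB) < 0) || any(c(pA, pB) > 1))
    stop("proportions must lie in [0, 1]")
  2 * (asin(sqrt(pA)) - asin(sqrt(pB)))
}

#' Characterise a cluster by per-feature effect sizes
#'
#' Compares the raw feature values of variants inside a cluster against
#' everything outside it (positives of other clusters combined with
#' negative controls): Cohen's h on the proportion of non-zero values for
#' binary features, Cohen's d for discrete and continuous features.  The
#' cluster's mean contribution profile is returned alongside.
#'
#' @param clusterX raw feature matrix of the cluster's variants.
#' @param restX raw feature matrix of the comparison set.
#' @param schema the [FeatureSchema-class] (supplies dtypes).
#' @param clusterContributions optional contribution matrix of the
#'   cluster's variants; its column means become `mean_profile`.
#' @return list with `effects` (`data.frame`: feature, kind, value) and
#'   `mean_profile` (or NULL).
#' @export
clusterVsRestEffects <- function(clusterX, restX, schema,
                                 clusterContributions = NULL) {
  stopifnot(nrow(clusterX) > 0L, nrow(restX) > 0L)
  dt <- featureDtypes(schema)
  effects <- do.call(rbind, lapply(featureNames(schema), function(fn) {
    a <- clusterX[, fn]; b <- restX[, fn]
    if (dt[[fn]] == "binary") {
      data.frame(feature = fn, kind = "cohen_h",
                 value = cohensH(mean(a != 0), mean(b != 0)))
    } else {
      data.frame(feature = fn, kind = "cohen_d", value = cohensD(a, b))
    }
  }))
  mp <- if (!is.null(clusterContributions))
    colMeans(clusterContributions)
  list(effects = effects, mean_profile = mp)
}

#' Per-cluster mean contribution profiles
#'
#' @param contributions contribution matrix (rows = variants).
#' @param assignment integer cluster assignment per row.
#' @return matrix: one row per cluster, columns = features.
#' @export
clusterMeanProfiles <- function(contributions, assignment) {
  t(vapply(sort(unique(assignment)), function(k)
    colMeans(contributions[assignment == k, , drop = FALSE]),
    numeric(ncol(contributions))))
}

#' Cluster composition at the decision threshold
#'
#' For positive-class variants grouped into clusters, tabulates how many
#' are recovered as true positives at the model threshold and how many are
#' missed (false negatives).
#'
#' @param scores scores of the clustered (positive) variants.
#' @param assignment cluster assignment per variant.
#' @param threshold decision threshold.
#' @return `data.frame`: cluster, n, true_positive, false_negative,
#'   tp_rate.
#' @export
clusterComposition <- function(scores, assignment, threshold) {
  do.call(rbind, lapply(sort(unique(assignment)), function(k) {
    s <- scores[assignment == k]
    data.frame(cluster = k, n = length(s),
               true_positive = sum(s >= threshold),
               false_negative = sum(s < threshold),
               tp_rate = mean(s >= threshold))
  }))
}
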