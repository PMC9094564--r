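#' @include AllClasses.R
NULL

samplingReport <- function(scheme, n_requested, n_obtained, positives,
                           negatives, genes = NULL, dropped = NULL,
                           warnings = character(0), tolerance = NA_real_) {
  per_biotype <- NULL
  if (!is.null(genes)) {
    bp <- table(assignBiotype(positives, genes))
    bn <- table(assignBiotype(negatives, genes))
    per_biotype <- data.frame(
      biotype = names(bp),
      positive_fraction = as.numeric(bp) / max(1L, length(positives)),
      negative_fraction = as.numeric(bn) / max(1L, length(negatives)))
  }
  structure(list(scheme = scheme, n_requested = n_requested,
                 n_obtained = n_obtained, per_biotype = per_biotype,
                 dropped_positives = dropped, warnings = warnings,
                 tolerance = tolerance),
            class = "SamplingReport")
}

#' @export
print.SamplingReport <- function(x, ...) {
  cat("SamplingReport [", x$scheme, "]: ", x$n_obtained, " of ",
      x$n_requested, " requested\n", sep = "")
  if (length(x$dropped_positives))
    cat("  dropped positives:", length(x$dropped_positives), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Random negative controls
#'
#' Uniform sampling without replacement from a pool of candidate benign
#' variants (the pool is expected to be pre-filtered to non-coding SNVs;
#' see [assignBiotype()] to exclude CDS variants).
#'
#' @param pool variant `GRanges` of candidate negatives.
#' @param n number of controls to draw.
#' @param seed integer seed; draws are bit-reproducible given the seed.
#' @return list with elements `variants` (the sampled `GRanges`, labelled
#'   `negative`) and `report` (a `SamplingReport`).
#' @export
sampleRandom <- function(pool, n, seed) {
  warnings <- character(0)
  if (n > length(pool)) {
    warnings <- sprintf("requested %d but pool has only %d", n, length(pool))
    idx <- seq_along(pool)
  } else {
    idx <- withSeed(seed, sample.int(length(pool), n))
  }
  out <- pool[sort(idx)]
  out$label <- rep_len("negative", length(out))
  list(variants = out,
       report = samplingReport("random", n, length(out), NULL, out,
                               warnings = warnings))
}

#' Local negative controls
#'
#' Keeps every pool variant lying within `window_bp` of at least one
#' positive variant on the same contig.  This builds the control set that
#' tests separation of classes at high genomic resolution.  Positives with
#' no eligible negative are reported in `dropped_positives`.
#'
#' @param pool variant `GRanges` of candidate negatives (non-coding SNVs).
#' @param positives positive variant `GRanges`.
#' @param window_bp maximum distance in bp (default 1000).
#' @param seed integer seed (used only when `per_positive_cap` limits the
#'   draw).
#' @param per_positive_cap optional cap on negatives kept per positive;
#'   default `Inf` keeps all eligible negatives.
#' @return list with `variants` and `report` (see [sampleRandom()]).
#' @export
sampleLocal <- function(pool, positives, window_bp = 1000L, seed = 1L,
                        per_positive_cap = Inf) {
  win <- GenomicRanges::resize(GenomicRanges::granges(positives),
                               width = 2L * window_bp + 1L, fix = "center")
  hits <- GenomicRanges::findOverlaps(pool, win)
  keep <- unique(S4Vectors::queryHits(hits))
  if (is.finite(per_positive_cap)) {
    sel <- withSeed(seed, {
      byPos <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
      unique(unlist(lapply(byPos, function(ix)
        if (length(ix) > per_positive_cap)
          sample(ix, per_positive_cap) else ix), use.names = FALSE))
    })
    keep <- intersect(keep, sel)
  }
  covered <- unique(S4Vectors::subjectHits(hits))
  dropped <- positives[setdiff(seq_along(positives), covered)]
  out <- pool[sort(keep)]
  out$label <- rep_len("negative", length(out))
  list(variants = out,
       report = samplingReport("local", NA_integer_, length(out),
                               positives, out, dropped = dropped))
}

#' Band- and biotype-adjusted negative controls
#'
#' The adjusted scheme corrects the location bias of naive negative
#' sampling: negatives are drawn only from cytogenetic bands that contain
#' at least one positive, and the biotype composition of the negatives is
#' matched to that of the positives so the classifier must learn functional
#' differences rather than genomic-location differences.  Per-biotype
#' quotas are `round(n_total * positive_fraction)` with largest-remainder
#' rounding so quotas sum to `n_total`; sampling within each stratum is
#' uniform without replacement.  Strata whose eligible pool is exhausted
#' are under-filled with a warning, and positives in such strata are
#' reported in `dropped_positives`.
#'
#' @param pool variant `GRanges` of candidate negatives (non-coding SNVs).
#' @param positives positive variant `GRanges`.
#' @param bands cytogenetic bands `GRanges` (with `band_name`).
#' @param genes a [GeneAnnotation-class] used for biotype assignment.
#' @param n_total total number of negatives to draw.
#' @param seed integer seed.
#' @param tolerance biotype proportion-matching tolerance recorded in the
#'   report (absolute; default 0.01).
#' @return list with `variants` and `report` (see [sampleRandom()]).
#' @export
sampleAdjusted <- function(pool, positives, bands, genes, n_total, seed,
                           tolerance = 0.01) {
  posBands <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(positives, bands)))
  inBand <- S4Vectors::queryHits(
    GenomicRanges::findOverlaps(pool, bands[posBands]))
  eligible <- sort(unique(inBand))

  posBio <- assignBiotype(positives, genes)
  poolBio <- assignBiotype(pool, genes)
  posCounts <- table(posBio)
  frac <- as.numeric(posCounts) / length(positives)
  ## largest-remainder quotas summing exactly to n_total
  raw <- n_total * frac
  quota <- floor(raw)
  rem <- n_total - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  names(quota) <- names(posCounts)

  warnings <- character(0)
  droppedBio <- character(0)
  take <- integer(0)
  seeds <- childSeeds(seed, length(quota))
  for (i in seq_along(quota)) {
    b <- names(quota)[i]
    if (quota[i] == 0L) next
    stratum <- eligible[poolBio[eligible] == b]
    if (length(stratum) < quota[i]) {
      warnings <- c(warnings, sprintf(
        "stratum '%s' exhausted: %d available of %d requested",
        b, length(stratum), quota[i]))
      droppedBio <- c(droppedBio, b)
      take <- c(take, stratum)
    } else {
      take <- c(take, withSeed(seeds[i],
                               stratum[sample.int(length(stratum), quota[i])]))
    }
  }
  out <- pool[sort(take)]
  out$label <- rep_len("negative", length(out))
  dropped <- positives[as.character(posBio) %in% droppedBio]
  list(variants = out,
       report = samplingReport("adjusted", n_total, length(out), positives,
                               out, genes = genes, dropped = dropped,
                               warnings = warnings, tolerance = tolerance))
}

#' Balanced per-tree training samples
#'
#' Class imbalance is handled at the tree level: each tree of the forest is
#' grown on its own balanced resample containing exactly `n` draws with
#' replacement from each class, where `n` is the size of the smaller class.
#' The per-tree membership is recorded and later used for out-of-bag
#' restriction of scores and contributions.
#'
#' @param y two-class factor or character vector of training labels.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return list of `n_trees` integer vectors of row indices (multisets of
#'   size `2n`, smaller-class first).
#' @export
balancedTreeSamples <- function(y, n_trees, seed) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("exactly two classes required for balanced sampling")
  idx <- split(seq_along(y), droplevels(y))
  n <- min(lengths(idx))
  withSeed(seed, lapply(seq_len(n_trees), function(t)
    unlist(lapply(idx, function(ix) ix[sample.int(length(ix), n,
                                                  replace = TRUE)]),
           use.names = FALSE)))
}
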