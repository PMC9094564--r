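#' @include core-io.R
NULL

#' Merge regulatory-region datasets into maximal regions
#'
#' Region-to-gene resources are integrated by unioning overlapping
#' intervals (a single shared base pair suffices; chains of overlaps merge
#' transitively) into maximal regions whose target-gene set and evidence
#' set are the unions over all constituent records.  Resources listed in
#' `passthrough` are exempt from merging and appended as-is — used for
#' resources whose per-region/target scoring would be destroyed by
#' merging.
#'
#' Merging is idempotent: merging the merged output changes nothing.
#'
#' @param datasets a `GRanges` with metadata columns `gene_id` and
#'   `source` (one row per region/gene pair, e.g. from
#'   [readRegionTable()]), or a list of such objects.
#' @param passthrough character vector of source names kept unmerged.
#' @return a `GRanges` of regions with metadata columns `target_genes`
#'   and `sources` (both `CharacterList`).
#' @export
mergeRegulatoryDatasets <- function(datasets, passthrough = character(0)) {
  if (is.list(datasets) && !inherits(datasets, "GRanges"))
    datasets <- suppressWarnings(do.call(c, unname(datasets)))
  keep <- !(datasets$source %in% passthrough)
  main <- datasets[keep]
  out <- GenomicRanges::GRanges()
  if (length(main)) {
    red <- GenomicRanges::reduce(main, with.revmap = TRUE,
                                 min.gapwidth = 0L)
    rv <- red$revmap
    red$target_genes <- IRanges::CharacterList(lapply(rv, function(ix)
      sort(unique(main$gene_id[ix]))))
    red$sources <- IRanges::CharacterList(lapply(rv, function(ix)
      sort(unique(main$source[ix]))))
    red$revmap <- NULL
    out <- red
  }
  pt <- datasets[!keep]
  if (length(pt)) {
    ptr <- GenomicRanges::granges(pt)
    ptr$target_genes <- IRanges::CharacterList(as.list(pt$gene_id))
    ptr$sources <- IRanges::CharacterList(as.list(pt$source))
    out <- suppressWarnings(c(out, ptr))
  }
  sort(out)
}

#' Filter scored variants by disease genes and rank them
#'
#' Keeps the variants that overlap at least one regulatory region whose
#' predicted target genes intersect the supplied disease-gene set, and
#' ranks the survivors by score, descending.  Ties are broken
#' deterministically by ascending (contig, position, alt allele).
#'
#' @param scored `data.frame` from [scoreVariants()] (columns `contig`,
#'   `pos`, `ref`, `alt`, `score`), or a variant `GRanges` with a `score`
#'   metadata column.
#' @param regions merged regions from [mergeRegulatoryDatasets()].
#' @param disease_genes non-empty character vector of gene ids; an empty
#'   set is an error (distinct from a valid query with no hits, which
#'   returns an empty result).
#' @return `data.frame`: contig, pos, ref, alt, score, matched_genes
#'   (comma-separated), rank (1-based permutation, scores non-increasing).
#' @export
filterByDiseaseGenes <- function(scored, regions, disease_genes) {
  if (!length(disease_genes)) stop("disease gene set is empty")
  if (is.data.frame(scored)) {
    gr <- GenomicRanges::GRanges(scored$contig,
                                 IRanges::IRanges(scored$pos, width = 1L))
    df <- scored
  } else {
    gr <- scored
    df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(scored)),
                     pos = GenomicRanges::start(scored),
                     ref = scored$ref, alt = scored$alt,
                     score = scored$score)
  }
  GenomeInfoDb::seqlevels(gr) <- normalizeContig(
    GenomeInfoDb::seqlevels(gr))
  subj <- regions
  GenomeInfoDb::seqlevels(subj) <- normalizeContig(
    GenomeInfoDb::seqlevels(subj))
  relevant <- which(vapply(regions$target_genes, function(g)
    any(g %in% disease_genes), logical(1)))
  hits <- GenomicRanges::findOverlaps(gr, subj[relevant])
  if (!length(hits)) return(rankedCandidateFrame(df[0, ], character(0)))
  qh <- S4Vectors::queryHits(hits)
  matched <- tapply(S4Vectors::subjectHits(hits), qh, function(ix)
    paste(sort(intersect(
      unique(unlist(regions$target_genes[relevant[ix]])),
      disease_genes)), collapse = ","))
  keep <- as.integer(names(matched))
  rankedCandidateFrame(df[keep, , drop = FALSE], as.character(matched))
}

rankedCandidateFrame <- function(df, matched_genes) {
  df$matched_genes <- matched_genes
  if (nrow(df)) {
    o <- order(-df$score, df$contig, df$pos, df$alt)
    df <- df[o, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
  } else {
    df$rank <- integer(0)
  }
  df
}

#' Spike-in ranking benchmark
#'
#' Emulates the clinical search for a causative regulatory mutation: known
#' pathogenic variants are seeded into a background of benign variants
#' from a reference genome, everything is restricted to variants inside
#' annotated regulatory regions, scored, filtered to regions targeting the
#' disease's genes, and ranked.  For each spiked-in variant the benchmark
#' reports its rank and the size of the per-disease candidate set; a
#' spike-in that falls in no region targeting its disease gene is flagged
#' unrankable rather than ranked.
#'
#' @param background benign variant `GRanges`.
#' @param backgroundX feature matrix of the background variants.
#' @param spikeIns pathogenic variant `GRanges` (absent from the
#'   background).
#' @param spikeX feature matrix of the spike-ins.
#' @param diseaseGenes list (one element per spike-in) of character
#'   vectors: the disease gene set associated with that variant.
#' @param model a [RegForestModel-class].
#' @param regions merged regulatory regions (see
#'   [mergeRegulatoryDatasets()]).
#' @return `data.frame`, one row per spike-in: contig, pos, score, rank
#'   (NA when unrankable), candidate_set_size, unrankable.
#' @export
spikeInBenchmark <- function(background, backgroundX, spikeIns, spikeX,
                             diseaseGenes, model, regions) {
  stopifnot(length(spikeIns) == length(diseaseGenes))
  bgKeys <- variantKey(background)
  if (any(variantKey(spikeIns) %in% bgKeys))
    stop("spike-in variants must be absent from the background")
  allVar <- c(GenomicRanges::granges(spikeIns),
              GenomicRanges::granges(background))
  allVar$ref <- c(spikeIns$ref, background$ref)
  allVar$alt <- c(spikeIns$alt, background$alt)
  inRegion <- IRanges::overlapsAny(allVar, regions)
  keep <- which(inRegion)
  Xall <- rbind(spikeX, backgroundX)
  scores <- rep(NA_real_, length(allVar))
  if (length(keep))
    scores[keep] <- scoreMatrix(model, Xall[keep, , drop = FALSE])
  scored <- data.frame(
    contig = as.character(GenomeInfoDb::seqnames(allVar))[keep],
    pos = GenomicRanges::start(allVar)[keep],
    ref = allVar$ref[keep], alt = allVar$alt[keep],
    score = scores[keep])
  spikeKeys <- variantKey(spikeIns)
  do.call(rbind, lapply(seq_along(spikeIns), function(i) {
    cand <- filterByDiseaseGenes(scored, regions, diseaseGenes[[i]])
    ckeys <- paste0(normalizeContig(cand$contig), ":", cand$pos, ":",
                    cand$ref, ">", cand$alt)
    j <- match(spikeKeys[i], ckeys)
    data.frame(contig = as.character(GenomeInfoDb::seqnames(spikeIns))[i],
               pos = GenomicRanges::start(spikeIns)[i],
               score = scores[i],
               rank = if (is.na(j)) NA_integer_ else cand$rank[j],
               candidate_set_size = nrow(cand),
               unrankable = is.na(j))
  }))
}
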