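## S4 classes for the central data objects.  Variants, bands, gene segments
## and regulatory regions are plain GRanges with documented metadata columns
## (the Bioconductor idiom); classes below are reserved for objects that
## carry real structure of their own.

#' @importClassesFrom GenomicRanges GRanges
NULL

#' FeatureSchema: the ordered feature catalogue of a model
#'
#' A `FeatureSchema` fixes, for the lifetime of a trained model, the ordered
#' list of features a variant is annotated with.  Each feature carries the
#' functional category it belongs to (`sequence`, `conservation`,
#' `functional_genomics`, `enhancer_gene_association`), its data type
#' (`binary`, `discrete`, `continuous`), the rule used to aggregate multiple
#' overlapping track intervals (`max`, `or`, `value`, `count`, `median`, or
#' `computed` for features derived from the variant itself such as the
#' substitution type), and the value imputed when no track covers the
#' position.
#'
#' @slot features a `data.frame` with columns `name`, `group`, `dtype`,
#'   `aggregation`, `missing_value`.
#' @seealso [defaultFeatureSchema()], [annotateVariants()]
#' @export
setClass("FeatureSchema", representation(features = "data.frame"))

setValidity("FeatureSchema", function(object) {
  f <- object@features
  need <- c("name", "group", "dtype", "aggregation", "missing_value")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(f$name)) return("feature names must be unique")
  if (!all(f$group %in% c("sequence", "conservation", "functional_genomics",
                          "enhancer_gene_association")))
    return("unknown feature group")
  if (!all(f$dtype %in% c("binary", "discrete", "continuous")))
    return("unknown feature dtype")
  if (!all(f$aggregation %in% c("max", "or", "value", "count", "median",
                                "computed")))
    return("unknown aggregation rule")
  if (!is.numeric(f$missing_value) || anyNA(f$missing_value))
    return("missing_value must be finite numeric")
  TRUE
})

#' IntervalTrack: a queryable interval-score annotation track
#'
#' Wraps a sorted set of genomic intervals with one or more value columns,
#' supporting point and range lookup.  Overlapping intervals are allowed and
#' all overlaps are returned, in input order.  This is the in-memory form of
#' a BED3+ / tabix-style tab-delimited track.
#'
#' @slot ranges a `GRanges` holding the intervals (1-based, closed, the
#'   Bioconductor convention; BED input is converted on read).
#' @slot values a `data.frame` of per-interval values, one row per interval.
#' @seealso [readIntervalTable()], [queryTrack()]
#' @export
setClass("IntervalTrack",
         representation(ranges = "GRanges", values = "data.frame"))

setValidity("IntervalTrack", function(object) {
  if (length(object@ranges) != nrow(object@values))
    return("ranges and values must have equal length")
  if (any(GenomicRanges::width(object@ranges) < 1L))
    return("zero- or negative-width interval")
  TRUE
})

#' GeneAnnotation: gene structures used for biotype assignment
#'
#' Holds the per-gene biotype segmentation (CDS, splice sites, UTRs,
#' promoters, non-coding exons, introns) used to assign every variant a
#' single biotype, plus transcription start sites.
#'
#' @slot segments `GRanges` with metadata columns `gene_id` and `biotype`.
#' @slot tss `GRanges` (width-1) with metadata columns `gene_id`, `symbol`.
#' @seealso [assignBiotype()]
#' @export
setClass("GeneAnnotation",
         representation(segments = "GRanges", tss = "GRanges"))

setValidity("GeneAnnotation", function(object) {
  if (anyDuplicated(object@tss$gene_id))
    return("gene_id must be unique in tss")
  ok <- c("CDS", "splice_site", "UTR", "promoter", "exon_noncoding", "intron")
  if (!all(object@segments$biotype %in% ok))
    return(paste("biotype must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' RegForestModel: a trained balanced random forest
#'
#' The forest is stored as an explicit list of trees (split variable, split
#' value, children, and the class-1 fraction of the tree's own balanced
#' training sample at every node), together with the per-tree training
#' multisets.  Node-level class fractions are what make the additive
#' decision-path decomposition of scores exact, and the per-tree sample
#' records are what make out-of-bag restriction possible for training
#' variants.
#'
#' @slot trees list of per-tree structures (`left`, `right`, `var`, `split`,
#'   `value`, `terminal`), node ids 1-based with node 1 the root.
#' @slot inbag list of integer vectors, one per tree: how many times each
#'   training row was drawn into that tree's balanced sample.
#' @slot schema the [FeatureSchema-class] the model was trained on.
#' @slot params list of forest hyperparameters (see [forestParams()]).
#' @slot threshold decision threshold on the score in (0,1); set to the
#'   F1-optimal value by [crossValidate()] or manually.
#' @slot classLevels the two class labels, negative first.
#' @slot nTraining number of training rows.
#' @slot engine the fitted ranger object (kept for fast batch prediction and
#'   cross-checks; may be NULL after [stripEngine()]).
#' @export
setClass("RegForestModel",
         representation(trees = "list", inbag = "list",
                        schema = "FeatureSchema", params = "list",
                        threshold = "numeric", classLevels = "character",
                        nTraining = "integer", engine = "ANY"))

setValidity("RegForestModel", function(object) {
  if (length(object@trees) != length(object@inbag))
    return("one inbag record per tree required")
  if (length(object@classLevels) != 2L)
    return("exactly two class levels required")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    return("threshold must lie in (0,1)")
  TRUE
})

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Defines the study conditions for the synthetic genome: its layout
#' (contigs, cytogenetic bands, genes, regulatory regions), the feature
#' schema size, the per-feature class effect sizes separating positive
#' (regulatory, damaging) from negative (benign) variants, the spatial
#' autocorrelation of feature noise, and the class sizes.
#'
#' @slot nContigs number of contigs.
#' @slot contigLength length of each contig in bp.
#' @slot nBandsPerContig cytogenetic bands per contig (bands tile contigs).
#' @slot nGenes number of genes.
#' @slot promoterSpan promoter length upstream of the TSS, bp.
#' @slot nRegions number of regulatory regions.
#' @slot targetsPerRegion target genes per regulatory region.
#' @slot nFeatures total number of schema features.
#' @slot informative names of informative continuous features.
#' @slot effectSize standardized mean shift (Cohen's d) applied to
#'   informative continuous features in the positive class.
#' @slot binaryRates named list of c(pPos, pNeg) pairs for binary features
#'   whose prevalence differs between classes.
#' @slot autocorLength window length (bp) of shared latent feature noise;
#'   variants in the same window share part of their noise.
#' @slot autocorWeight fraction of continuous-feature variance carried by
#'   the shared window noise, in [0,1).
#' @slot nPositives number of positive (damaging) variants.
#' @slot nNegativePool size of the benign variant pool negatives are drawn
#'   from.
#' @slot poolGeneBias fraction of the benign pool drawn from gene-proximal
#'   segments rather than uniformly, emulating the gene-centric
#'   ascertainment of clinical variant databases.
#' @slot seed master seed.
#' @seealso [simulationConfig()], [simulateLayout()], [simulateVariants()]
#' @export
setClass("SimulationConfig",
         representation(nContigs = "integer", contigLength = "integer",
                        nBandsPerContig = "integer", nGenes = "integer",
                        promoterSpan = "integer", nRegions = "integer",
                        targetsPerRegion = "integer", nFeatures = "integer",
                        informative = "character", effectSize = "numeric",
                        binaryRates = "list", autocorLength = "integer",
                        autocorWeight = "numeric", nPositives = "integer",
                        nNegativePool = "integer", poolGeneBias = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  counts <- c(object@nContigs, object@contigLength, object@nBandsPerContig,
              object@nGenes, object@nRegions, object@targetsPerRegion,
              object@nFeatures, object@nPositives, object@nNegativePool)
  if (any(counts <= 0L)) return("all counts must be positive")
  if (!all(is.finite(object@effectSize))) return("effect sizes must be finite")
  if (object@autocorWeight < 0 || object@autocorWeight >= 1)
    return("autocorWeight must lie in [0,1)")
  if (object@poolGeneBias < 0 || object@poolGeneBias > 1)
    return("poolGeneBias must lie in [0,1]")
  TRUE
})
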