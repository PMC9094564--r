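#' @include AllClasses.R
NULL

CHROMATIN_STATES <- c(
  "TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk", "EnhG1", "EnhG2",
  "EnhA1", "EnhA2", "EnhWk", "ZNF_Rpts", "Het", "TssBiv", "EnhBiv",
  "ReprPC", "ReprPCWk", "Quies")

BIOTYPE_PRIORITY <- c("CDS", "splice_site", "UTR", "promoter",
                      "exon_noncoding", "intron", "intergenic")

#' Construct a FeatureSchema
#'
#' @param features `data.frame` with columns `name`, `group`, `dtype`,
#'   `aggregation`, `missing_value`.
#' @return a [FeatureSchema-class].
#' @export
FeatureSchema <- function(features) {
  features$name <- as.character(features$name)
  methods::new("FeatureSchema", features = features)
}

#' The default 41-feature schema
#'
#' The shipped schema mirrors a compendium of 41 per-variant annotations in
#' four functional categories: three sequence features (substitution type
#' and CpG context), seven evolutionary-conservation scores, twenty-four
#' functional-genomics features (18 chromatin-state cell-type counts, three
#' histone-mark median fold changes, TFBS and DNase overlaps), and seven
#' regulatory-region / enhancer-gene association overlaps.  Feature sources
#' are configurable: the schema carries the aggregation rule and missing
#' value for each feature, not the tracks themselves.
#'
#' Missing-value policy: every feature defaults to 0, encoding "no
#' evidence" — no signal, no conservation, no overlap.  Random forests
#' require finite values and 0 is the natural absence code for all feature
#' families used here.
#'
#' @return a [FeatureSchema-class] with 41 features.
#' @examples
#' sch <- defaultFeatureSchema()
#' nFeatures(sch)
#' @export
defaultFeatureSchema <- function() {
  f <- rbind(
    data.frame(name = "variant_type", group = "sequence", dtype = "discrete",
               aggregation = "computed", missing_value = 0),
    data.frame(name = c("CpG_dinucleotide", "CpG_island"),
               group = "sequence", dtype = "binary", aggregation = "or",
               missing_value = 0),
    data.frame(name = c("phyloP_vertebrates", "phastCons_vertebrates",
                        "phyloP_primates", "phastCons_primates",
                        "GERP_score", "GERP_element", "CDTS"),
               group = "conservation",
               dtype = c("continuous", "continuous", "continuous",
                         "continuous", "continuous", "binary", "continuous"),
               aggregation = c("value", "value", "value", "value", "value",
                               "or", "value"),
               missing_value = 0),
    data.frame(name = paste0("state_", CHROMATIN_STATES),
               group = "functional_genomics", dtype = "discrete",
               aggregation = "value", missing_value = 0),
    data.frame(name = c("H3K4me1_median", "H3K4me3_median",
                        "H3K27ac_median"),
               group = "functional_genomics", dtype = "continuous",
               aggregation = "median", missing_value = 0),
    data.frame(name = c("TFBS_conserved", "TFBS_cluster_max_score",
                        "TFBS_jaspar"),
               group = "functional_genomics",
               dtype = c("binary", "continuous", "binary"),
               aggregation = c("or", "max", "or"), missing_value = 0),
    data.frame(name = "DNase_cluster", group = "functional_genomics",
               dtype = "binary", aggregation = "or", missing_value = 0),
    data.frame(name = c("GeneHancer", "PEGASUS", "FANTOM5", "FOCS",
                        "promoter_2kb", "UTR_overlap"),
               group = "enhancer_gene_association", dtype = "binary",
               aggregation = "or", missing_value = 0))
  FeatureSchema(f)
}

#' Read a feature schema from a YAML or JSON config
#'
#' The config is a list of feature entries with fields `name`, `group`,
#' `dtype`, `aggregation`, `missing_value` (and optionally `track`, the
#' path of the source track, returned as an attribute).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a [FeatureSchema-class]; track paths, if present, in
#'   `attr(, "tracks")`.
#' @export
readFeatureSchema <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(cfg, function(e)
    data.frame(name = e$name, group = e$group, dtype = e$dtype,
               aggregation = e$aggregation %||% "value",
               missing_value = as.numeric(e$missing_value %||% 0)))
  sch <- FeatureSchema(do.call(rbind, rows))
  tracks <- vapply(cfg, function(e) e$track %||% NA_character_, character(1))
  names(tracks) <- featureNames(sch)
  attr(sch, "tracks") <- tracks
  sch
}

#' Aggregate per-cell-type chromatin states at one position
#'
#' Chromatin-state calls are sparse: each cell type assigns the position a
#' single state from an 18-state alphabet.  To make them usable by a random
#' forest, they are aggregated into a count per state: the number of cell
#' types in each state at the position.
#'
#' @param states named character vector: cell type -> state call at the
#'   position (cell types without a call simply absent).
#' @param state_alphabet the state alphabet; defaults to the 18-state
#'   chromatin model.
#' @return named integer vector of cell-type counts over the alphabet;
#'   counts sum to `length(states)`.
#' @examples
#' aggregateChromatinStates(c(ctA = "EnhA1", ctB = "Quies"))
#' @export
aggregateChromatinStates <- function(states,
                                     state_alphabet = CHROMATIN_STATES) {
  counts <- stats::setNames(integer(length(state_alphabet)), state_alphabet)
  if (length(states)) {
    states <- as.character(states)
    bad <- setdiff(unique(states), state_alphabet)
    if (length(bad)) stop("state outside alphabet: ", bad[1])
    tab <- table(factor(states, levels = state_alphabet))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Median signal across cell types
#'
#' Median of a fold-change signal across cell types at one position (mean
#' of the two central order statistics for even n); an empty vector maps to
#' the supplied missing value.
#'
#' @param values numeric vector (possibly empty).
#' @param missing_value value returned for empty input (default 0).
#' @return a single number.
#' @export
medianSignal <- function(values, missing_value = 0) {
  if (!length(values)) return(missing_value)
  stats::median(values)
}

#' Assign each variant a single biotype
#'
#' When a variant overlaps several gene segments the most constrained
#' annotation wins, under the fixed priority
#' CDS > splice_site > UTR > promoter > exon_noncoding > intron; variants
#' overlapping no segment are `intergenic`.
#'
#' @param variants a variant `GRanges` (or any `GRanges`).
#' @param genes a [GeneAnnotation-class].
#' @return factor of biotypes with levels in priority order.
#' @export
assignBiotype <- function(variants, genes) {
  segs <- genes@segments
  pr <- match(segs$biotype, BIOTYPE_PRIORITY)
  hits <- GenomicRanges::findOverlaps(variants, segs)
  best <- rep(NA_integer_, length(variants))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    ph <- pr[S4Vectors::subjectHits(hits)]
    agg <- tapply(ph, qh, min)
    best[as.integer(names(agg))] <- as.integer(agg)
  }
  best[is.na(best)] <- match("intergenic", BIOTYPE_PRIORITY)
  factor(BIOTYPE_PRIORITY[best], levels = BIOTYPE_PRIORITY)
}

#' Annotate variants into feature vectors
#'
#' Turns each variant into the fixed-length numeric vector the classifier
#' consumes.  Features with aggregation `computed` are derived from the
#' variant itself (currently `variant_type`: 1 = transition,
#' 2 = transversion, 3 = indel).  All other features are looked up in their
#' named track at the variant position, applying the schema's aggregation
#' rule across overlapping intervals: `max`/`value` take the maximum
#' overlapping value, `or` any non-zero overlap, `count` the number of
#' overlapping intervals, `median` the median of overlapping values.
#' Positions covered by no interval receive the feature's missing value.
#'
#' Annotation is pure: the same (variants, tracks, schema) always yields
#' the same matrix, with columns in schema order.
#'
#' @param variants a variant `GRanges`.
#' @param tracks named list of [IntervalTrack-class], keyed by feature name.
#'   Every non-computed schema feature must be present (checked before any
#'   variant is processed).
#' @param schema a [FeatureSchema-class].
#' @return numeric matrix, one row per variant, columns named and ordered
#'   by the schema.
#' @export
annotateVariants <- function(variants, tracks, schema = defaultFeatureSchema()) {
  agg <- featureAggregations(schema)
  miss <- missingValues(schema)
  fnames <- featureNames(schema)
  needed <- fnames[agg != "computed"]
  absent <- setdiff(needed, names(tracks))
  if (length(absent))
    stop("no track supplied for feature(s): ", paste(absent, collapse = ", "))
  X <- matrix(rep(miss, each = length(variants)),
              nrow = length(variants), ncol = length(fnames),
              dimnames = list(NULL, fnames))
  q <- GenomicRanges::granges(variants)
  GenomeInfoDb::seqlevels(q) <- normalizeContig(GenomeInfoDb::seqlevels(q))
  for (fn in fnames) {
    if (agg[[fn]] == "computed") {
      if (fn == "variant_type") {
        X[, fn] <- match(variants$variantType,
                         c("transition", "transversion", "indel"))
      } else stop("no rule to compute feature: ", fn)
      next
    }
    tr <- tracks[[fn]]
    subj <- tr@ranges
    GenomeInfoDb::seqlevels(subj) <- normalizeContig(
      GenomeInfoDb::seqlevels(subj))
    hits <- GenomicRanges::findOverlaps(q, subj)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    v <- if (ncol(tr@values)) as.numeric(tr@values[[1]][
      S4Vectors::subjectHits(hits)]) else rep(1, length(hits))
    val <- switch(agg[[fn]],
      max = , value = tapply(v, qh, max),
      or = tapply(v, qh, function(z) as.numeric(any(z != 0))),
      count = tapply(v, qh, length),
      median = tapply(v, qh, stats::median))
    X[as.integer(names(val)), fn] <- as.numeric(val)
  }
  X
}

#' Write an annotated variant matrix as TSV
#'
#' @param variants variant `GRanges`.
#' @param X feature matrix from [annotateVariants()].
#' @param path output path.
#' @param comment optional header comment.
#' @return the path, invisibly.
#' @export
writeAnnotatedTsv <- function(variants, X, path, comment = NULL) {
  df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(variants)),
                   pos = GenomicRanges::start(variants),
                   ref = variants$ref, alt = variants$alt,
                   label = variants$label, check.names = FALSE)
  writeTsv(cbind(df, as.data.frame(X, check.names = FALSE)), path, comment)
}
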