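#' @include AllClasses.R
NULL

#' Construct a variant set
#'
#' Variants are represented as a width-1 `GRanges` anchored at the VCF
#' (1-based) position, with metadata columns `ref`, `alt`, `label`
#' (`positive` / `negative` / `unknown`) and `variantType` (`transition` /
#' `transversion` / `indel`).  For indels the range still has width 1 at the
#' anchor base; the positions an indel affects are enumerated at scoring
#' time (see [scoreIndel()]).
#'
#' @param contig character vector of contig names.
#' @param pos 1-based positions (VCF convention).
#' @param ref,alt allele strings over A/C/G/T.
#' @param label class labels, recycled; default `"unknown"`.
#' @return a `GRanges` of variants.
#' @examples
#' makeVariants("chr1", c(100, 200), c("A", "C"), c("G", "CT"))
#' @export
makeVariants <- function(contig, pos, ref, alt, label = "unknown") {
  ref <- rep_len(as.character(ref), length(pos))
  alt <- rep_len(as.character(alt), length(pos))
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = pos, width = 1L))
  gr$ref <- as.character(ref)
  gr$alt <- as.character(alt)
  gr$label <- rep_len(as.character(label), length(gr))
  gr$variantType <- mapply(classifyVariantType, gr$ref, gr$alt,
                           USE.NAMES = FALSE)
  gr
}

#' Classify a substitution as transition, transversion or indel
#'
#' A substitution is a transition when both alleles are purines (A/G) or
#' both pyrimidines (C/T), a transversion when one is a purine and the other
#' a pyrimidine, and an indel when allele lengths differ.
#'
#' @param ref,alt single allele strings over A/C/G/T.
#' @return one of `"transition"`, `"transversion"`, `"indel"`.
#' @examples
#' classifyVariantType("A", "G")  # transition
#' classifyVariantType("C", "A")  # transversion
#' classifyVariantType("A", "AT") # indel
#' @export
classifyVariantType <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt) ||
      grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must be non-empty A/C/G/T strings")
  if (ref == alt) stop("invalid variant: ref and alt are identical")
  if (nchar(ref) != nchar(alt)) return("indel")
  if (nchar(ref) > 1L) {
    ## equal-length multi-base substitution: classify by the first
    ## differing base pair
    rs <- strsplit(ref, "")[[1]]; as <- strsplit(alt, "")[[1]]
    i <- which(rs != as)[1]
    ref <- rs[i]; alt <- as[i]
  }
  purine <- c("A", "G")
  if ((ref %in% purine) == (alt %in% purine)) "transition" else "transversion"
}

#' Read variants from a VCF file
#'
#' Reads a (plain or bgzip) VCF and returns one variant per (record,
#' alternate allele): multi-allelic records are split and each allele is
#' handled independently downstream.  Records whose REF contains characters
#' other than A/C/G/T (e.g. symbolic alleles) are skipped with a warning.
#'
#' @param path path to a VCF file.
#' @param label class label assigned to all read variants
#'   (default `"unknown"`).
#' @return a `GRanges` of variants (see [makeVariants()]), in file order.
#' @export
readVariants <- function(path, label = "unknown") {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0L)
    return(makeVariants(character(0), integer(0), character(0), character(0)))
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  bad <- grepl("[^ACGT]", toupper(ref)) | grepl("[^ACGT]", toupper(alt)) |
    !nzchar(ref) | !nzchar(alt)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-ACGT alleles skipped")
    rr <- rr[!bad]; ref <- ref[!bad]; alt <- alt[!bad]
  }
  makeVariants(as.character(GenomeInfoDb::seqnames(rr)),
               GenomicRanges::start(rr), ref, alt, label = label)
}

#' Write variants to a minimal VCF
#'
#' Emits a VCF v4.2 body with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns;
#' positions are written 1-based exactly as stored, so a read/write cycle
#' round-trips coordinates.
#'
#' @param variants a variant `GRanges`.
#' @param path output path.
#' @param comment optional extra `##` header line.
#' @return the path, invisibly.
#' @export
writeVariantsVcf <- function(variants, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(comment)) writeLines(paste0("##", comment), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (length(variants))
    writeLines(paste(as.character(GenomeInfoDb::seqnames(variants)),
                     GenomicRanges::start(variants), ".",
                     variants$ref, variants$alt, ".", ".", ".",
                     sep = "\t"), con)
  invisible(path)
}

#' Read a BED-style interval table into a queryable track
#'
#' The first three columns must follow the BED convention (contig, 0-based
#' start, exclusive end), sorted by start within each contig; remaining
#' columns are per-interval values.  Coordinates are converted to the
#' 1-based closed convention used internally, so a BED interval
#' `[start, end)` covers 1-based positions `start+1 .. end`.
#'
#' @param path tab-delimited file, optionally with `#`-prefixed header.
#' @param value_columns names for the value columns; defaults to `V4`, ...
#' @return an [IntervalTrack-class].
#' @export
readIntervalTable <- function(path, value_columns = NULL) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) stop("empty interval table: ", path)
  dt <- data.table::fread(text = paste(ln, collapse = "\n"), sep = "\t",
                          header = FALSE, data.table = FALSE)
  contig <- as.character(dt[[1]])
  start0 <- as.numeric(dt[[2]]); end0 <- as.numeric(dt[[3]])
  if (any(start0 >= end0)) {
    i <- which(start0 >= end0)[1]
    stop("start >= end at line ", i, " of ", path)
  }
  ooo <- which(diff(start0) < 0 & contig[-1] == contig[-length(contig)])
  if (length(ooo))
    stop("intervals not sorted within contig at line ", ooo[1] + 1L,
         " of ", path)
  vals <- dt[-(1:3)]
  if (is.null(value_columns)) value_columns <- paste0("V", seq_along(vals) + 3L)
  if (ncol(vals)) names(vals) <- rep_len(value_columns, ncol(vals))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0))
  methods::new("IntervalTrack", ranges = gr, values = vals)
}

#' Build an IntervalTrack in memory
#'
#' @param contig,start,end interval coordinates (1-based, closed).
#' @param values a `data.frame` (or vector) of per-interval values.
#' @return an [IntervalTrack-class].
#' @export
intervalTrack <- function(contig, start, end, values) {
  if (!is.data.frame(values)) values <- data.frame(value = values)
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = start, end = end))
  methods::new("IntervalTrack", ranges = gr, values = values)
}

#' Query a track at genomic positions
#'
#' Returns, for each query position, the values of all intervals covering
#' it, in track input order.  Contig names are matched after stripping any
#' `chr` prefix on either side.
#'
#' @param track an [IntervalTrack-class].
#' @param contig contig name(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @param column which value column to return (default the first).
#' @return a list with one numeric vector of values per query position
#'   (empty vector when nothing overlaps).
#' @export
queryTrack <- function(track, contig, pos, column = 1L) {
  q <- GenomicRanges::GRanges(normalizeContig(contig),
                              IRanges::IRanges(start = pos, width = 1L))
  subj <- track@ranges
  GenomeInfoDb::seqlevels(subj) <- normalizeContig(
    GenomeInfoDb::seqlevels(subj))
  hits <- GenomicRanges::findOverlaps(q, subj)
  v <- track@values[[column]]
  out <- rep(list(numeric(0)), length(q))
  if (length(hits)) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (k in names(sp)) out[[as.integer(k)]] <- v[sort(sp[[k]])]
  }
  out
}

#' Read cytogenetic bands from a BED-like table
#'
#' Expects columns contig, start (0-based), end, band name.  Bands on a
#' contig must be non-overlapping and sorted.
#'
#' @param path tab-delimited file.
#' @return a `GRanges` with metadata column `band_name`.
#' @export
readBands <- function(path) {
  tr <- readIntervalTable(path, value_columns = "band_name")
  gr <- tr@ranges
  gr$band_name <- as.character(tr@values$band_name)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(ov)) stop("cytogenetic bands overlap")
  gr
}

#' Assemble a GeneAnnotation
#'
#' @param segments `GRanges` with metadata columns `gene_id`, `biotype`
#'   (one of CDS, splice_site, UTR, promoter, exon_noncoding, intron).
#' @param tss width-1 `GRanges` with `gene_id` and `symbol`.
#' @return a [GeneAnnotation-class].
#' @export
geneAnnotation <- function(segments, tss) {
  methods::new("GeneAnnotation", segments = segments, tss = tss)
}

#' Read regulatory region -> target gene tables
#'
#' Each row links one interval (BED-convention coordinates) to one target
#' gene, with a source column naming the evidence resource.
#'
#' @param path TSV with columns `contig`, `start`, `end`, `gene_id`,
#'   `source`.
#' @return a `GRanges` with metadata columns `gene_id` and `source`
#'   (one row per region/gene pair, 1-based closed coordinates).
#' @export
readRegionTable <- function(path) {
  df <- readTsv(path)
  need <- c("contig", "start", "end", "gene_id", "source")
  if (!all(need %in% names(df)))
    stop("region table needs columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(start = df$start + 1L,
                                                end = df$end))
  gr$gene_id <- as.character(df$gene_id)
  gr$source <- as.character(df$source)
  gr
}
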