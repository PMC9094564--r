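#' @include annotation.R ranking.R
NULL

#' Construct a synthetic-data configuration
#'
#' Defaults define a desk-scale study: 2 contigs of 10 Mb tiled by 20
#' cytogenetic bands each, 200 genes with promoter/UTR/CDS/intron/splice
#' structure, 500 regulatory regions with target genes, a 41-feature
#' schema with 5 informative conservation-type features shifted by
#' Cohen's d = 3 in the positive class, spatially autocorrelated
#' continuous-feature noise (2 kb windows carrying half the noise
#' variance), 800 positive variants biased toward gene-proximal biotypes,
#' and a 50,000-variant uniform benign pool.
#'
#' @param nContigs,contigLength,nBandsPerContig,nGenes,promoterSpan
#'   genome layout; see [SimulationConfig-class].
#' @param nRegions,targetsPerRegion regulatory regions.
#' @param nFeatures schema size (41 = the default schema).
#' @param informative names of informative continuous features.
#' @param effectSize standardized shift of informative features in
#'   positives.
#' @param binaryRates named list of `c(pPos, pNeg)` prevalence pairs for
#'   binary features; features not listed use equal prevalence in both
#'   classes.
#' @param autocorLength,autocorWeight spatial autocorrelation window (bp)
#'   and the fraction of continuous-noise variance shared within a window.
#' @param nPositives,nNegativePool class sizes.
#' @param poolGeneBias fraction of the benign pool placed in gene-proximal
#'   segments (promoters, UTRs, introns) rather than uniformly over the
#'   contigs; clinical benign-variant databases are strongly enriched near
#'   genes, and without this enrichment biotype-matched sampling would
#'   exhaust its gene-proximal strata.  Positives remain substantially
#'   more gene-proximal than the pool.
#' @param seed master seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nContigs = 2L, contigLength = 10000000L,
                             nBandsPerContig = 20L, nGenes = 200L,
                             promoterSpan = 2000L, nRegions = 500L,
                             targetsPerRegion = 2L, nFeatures = 41L,
                             informative = c("GERP_score",
                                             "phyloP_vertebrates",
                                             "phastCons_vertebrates",
                                             "CDTS",
                                             "TFBS_cluster_max_score"),
                             effectSize = 3,
                             binaryRates = list(),
                             autocorLength = 2000L, autocorWeight = 0.5,
                             nPositives = 800L, nNegativePool = 50000L,
                             poolGeneBias = 0.4, seed = 1L) {
  methods::new("SimulationConfig", nContigs = as.integer(nContigs),
               contigLength = as.integer(contigLength),
               nBandsPerContig = as.integer(nBandsPerContig),
               nGenes = as.integer(nGenes),
               promoterSpan = as.integer(promoterSpan),
               nRegions = as.integer(nRegions),
               targetsPerRegion = as.integer(targetsPerRegion),
               nFeatures = as.integer(nFeatures),
               informative = informative, effectSize = effectSize,
               binaryRates = binaryRates,
               autocorLength = as.integer(autocorLength),
               autocorWeight = autocorWeight,
               nPositives = as.integer(nPositives),
               nNegativePool = as.integer(nNegativePool),
               poolGeneBias = poolGeneBias,
               seed = as.integer(seed))
}

## Gene model used by the generator: promoter, 5'UTR, three CDS exons
## separated by introns (2 bp splice sites at each junction), 3'UTR.
geneSegmentWidths <- function(promoterSpan) {
  c(promoter = promoterSpan, UTR = 200L, CDS = 300L, intron = 1500L,
    CDS = 300L, intron = 1500L, CDS = 300L, UTR = 200L)
}

#' Simulate the genome layout
#'
#' Builds contigs, cytogenetic bands exactly tiling each contig, genes
#' with biotype segments (promoter = `promoterSpan` bp upstream of the
#' TSS, UTRs, CDS exons, introns with 2 bp splice sites), and regulatory
#' regions placed within 50 kb of gene TSSs, each targeting its anchor
#' gene plus nearby genes.
#'
#' @param cfg a [SimulationConfig-class].
#' @return list with `contigs` (named lengths), `bands` (`GRanges` with
#'   `band_name`), `genes` (a [GeneAnnotation-class]), `regionPairs`
#'   (`GRanges`, one row per region/gene/source) and `regions` (the
#'   merged `GRanges` with `target_genes`).
#' @export
simulateLayout <- function(cfg) {
  validObject(cfg)
  contigs <- stats::setNames(rep(cfg@contigLength, cfg@nContigs),
                             paste0("chr", seq_len(cfg@nContigs)))
  seeds <- childSeeds(cfg@seed, 3L)

  ## bands tile each contig exactly
  bands <- suppressWarnings(do.call(c, lapply(names(contigs), function(ct) {
    bw <- floor(contigs[[ct]] / cfg@nBandsPerContig)
    st <- (seq_len(cfg@nBandsPerContig) - 1L) * bw + 1L
    en <- c(st[-1L] - 1L, contigs[[ct]])
    gr <- GenomicRanges::GRanges(ct, IRanges::IRanges(st, en))
    gr$band_name <- sprintf("%sq%02d", sub("chr", "", ct),
                            seq_len(cfg@nBandsPerContig))
    gr
  })))

  ## genes: one per slot, random offset within the slot
  widths <- geneSegmentWidths(cfg@promoterSpan)
  span <- sum(widths)
  perContig <- ceiling(cfg@nGenes / cfg@nContigs)
  slot <- floor(cfg@contigLength / perContig)
  if (slot < span + 100L)
    stop("geometry impossible: ", cfg@nGenes, " genes of span ", span,
         " bp do not fit ", cfg@nContigs, " x ", cfg@contigLength, " bp")
  gidx <- 0L
  segs <- list(); tss <- list()
  offsets <- withSeed(seeds[1L],
                      sample.int(slot - span - 1L, cfg@nGenes,
                                 replace = TRUE))
  for (ct in names(contigs)) {
    for (i in seq_len(perContig)) {
      if (gidx >= cfg@nGenes) break
      gidx <- gidx + 1L
      g0 <- (i - 1L) * slot + offsets[gidx]
      ends <- g0 + cumsum(widths)
      starts <- c(g0 + 1L, head(ends, -1L) + 1L)
      gid <- sprintf("G%04d", gidx)
      sg <- GenomicRanges::GRanges(ct, IRanges::IRanges(starts, ends))
      sg$gene_id <- gid
      sg$biotype <- names(widths)
      ## 2 bp splice sites just inside each intron boundary
      intr <- which(names(widths) == "intron")
      ss <- GenomicRanges::GRanges(ct, IRanges::IRanges(
        c(starts[intr], ends[intr] - 1L),
        c(starts[intr] + 1L, ends[intr])))
      ss$gene_id <- gid
      ss$biotype <- "splice_site"
      segs[[gidx]] <- c(sg, ss)
      tg <- GenomicRanges::GRanges(ct, IRanges::IRanges(starts[2L],
                                                        width = 1L))
      tg$gene_id <- gid
      tg$symbol <- gid
      tss[[gidx]] <- tg
    }
  }
  genes <- suppressWarnings(
    geneAnnotation(do.call(c, segs), do.call(c, tss)))

  ## regulatory regions near gene TSSs
  tssAll <- genes@tss
  regionSources <- c("coexpression", "conservation_linkage",
                     "chromatin_contact")
  rp <- withSeed(seeds[2L], {
    anchor <- sample.int(length(tssAll), cfg@nRegions, replace = TRUE)
    offset <- sample(-50000:50000, cfg@nRegions, replace = TRUE)
    rw <- sample(500:2000, cfg@nRegions, replace = TRUE)
    st <- pmax(1L, GenomicRanges::start(tssAll)[anchor] + offset)
    ct <- as.character(GenomeInfoDb::seqnames(tssAll))[anchor]
    st <- pmin(st, contigs[ct] - rw)
    src <- sample(regionSources, cfg@nRegions, replace = TRUE)
    pairs <- lapply(seq_len(cfg@nRegions), function(r) {
      ## targets: anchor gene plus nearest genes on the same contig
      onCt <- which(as.character(GenomeInfoDb::seqnames(tssAll)) == ct[r])
      dd <- abs(GenomicRanges::start(tssAll)[onCt] - st[r])
      tg <- unique(c(anchor[r],
                     onCt[order(dd)][seq_len(cfg@targetsPerRegion)]))
      tg <- tg[seq_len(min(length(tg), cfg@targetsPerRegion))]
      gr <- GenomicRanges::GRanges(ct[r],
        IRanges::IRanges(rep(st[r], length(tg)), width = rw[r]))
      gr$gene_id <- tssAll$gene_id[tg]
      gr$source <- src[r]
      gr
    })
    suppressWarnings(do.call(c, pairs))
  })
  ## promoters and UTRs are regulatory regions of interest in their own
  ## right, targeting their own gene
  promUtr <- genes@segments[genes@segments$biotype %in% c("promoter", "UTR")]
  pu <- GenomicRanges::granges(promUtr)
  pu$gene_id <- promUtr$gene_id
  pu$source <- "promoter_utr"
  rp <- suppressWarnings(c(rp, pu))
  regions <- mergeRegulatoryDatasets(rp)

  list(contigs = contigs, bands = bands, genes = genes,
       regionPairs = rp, regions = regions)
}

randomAlleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  transitionOf <- c(A = "G", G = "A", C = "T", T = "C")
  isTi <- runif(n) < 2 / 3
  alt <- character(n)
  alt[isTi] <- transitionOf[ref[isTi]]
  tv <- !isTi
  alt[tv] <- vapply(ref[tv], function(r)
    sample(setdiff(c("A", "C", "G", "T"),
                   c(r, transitionOf[[r]])), 1L), character(1))
  list(ref = ref, alt = alt)
}

#' Class-conditional feature values for a set of variants
#'
#' Draws feature values per the configuration: continuous features are
#' standard normal noise plus the configured shift for informative
#' features in positives, with a fraction `autocorWeight` of the noise
#' variance shared by all variants in the same `autocorLength` window of
#' the genome (nearby variants therefore share part of their feature
#' noise); binary features are Bernoulli with class-specific rates where
#' configured (0.15 in both classes otherwise); discrete features are
#' Poisson counts (cell-type-count-like); the `variant_type` feature is
#' computed from the alleles, not drawn.
#'
#' @param cfg a [SimulationConfig-class].
#' @param variants variant `GRanges`.
#' @param labels "positive"/"negative" per variant.
#' @param seed integer seed.
#' @param schema feature schema (default [defaultFeatureSchema()]).
#' @return numeric matrix, columns in schema order.
#' @export
simulateFeatures <- function(cfg, variants, labels, seed,
                             schema = defaultFeatureSchema()) {
  n <- length(variants)
  pos <- labels == "positive"
  dt <- featureDtypes(schema)
  agg <- featureAggregations(schema)
  fnames <- featureNames(schema)
  win <- paste0(normalizeContig(GenomeInfoDb::seqnames(variants)), ":",
                GenomicRanges::start(variants) %/% cfg@autocorLength)
  wid <- match(win, unique(win))
  nw <- max(wid)
  w <- cfg@autocorWeight
  withSeed(seed, {
    X <- matrix(0, n, length(fnames), dimnames = list(NULL, fnames))
    for (fn in fnames) {
      if (agg[[fn]] == "computed") {
        X[, fn] <- match(variants$variantType,
                         c("transition", "transversion", "indel"))
      } else if (dt[[fn]] == "binary") {
        r <- cfg@binaryRates[[fn]] %||% c(0.15, 0.15)
        X[, fn] <- rbinom(n, 1L, ifelse(pos, r[1L], r[2L]))
      } else if (dt[[fn]] == "discrete") {
        X[, fn] <- rpois(n, 1)
      } else {
        z <- rnorm(nw)
        eps <- sqrt(1 - w) * rnorm(n) + sqrt(w) * z[wid]
        mu <- if (fn %in% cfg@informative) cfg@effectSize * pos else 0
        X[, fn] <- mu + eps
      }
    }
    X
  })
}

#' Simulate labelled variants with features and ground truth
#'
#' Positive variants are biased toward gene-proximal biotypes (drawn
#' inside promoter, UTR and intron segments, in clumps of 1-3 variants a
#' few hundred bp apart, mimicking the clustering of curated damaging
#' mutations); pool negatives are uniform over the contigs.  Positions in
#' CDS or splice sites are excluded from both classes and all positions
#' are distinct.  Features come from [simulateFeatures()].
#'
#' @param cfg a [SimulationConfig-class].
#' @param layout output of [simulateLayout()].
#' @return list with `variants` (positives first, then the pool; `label`
#'   column set), `X` (feature matrix), and `truth` (list: informative
#'   feature names, effect size, labels).
#' @export
simulateVariants <- function(cfg, layout) {
  seeds <- childSeeds(cfg@seed, 4L)
  genes <- layout$genes
  segs <- genes@segments
  proximal <- segs[segs$biotype %in% c("promoter", "UTR", "intron")]
  coding <- segs[segs$biotype %in% c("CDS", "splice_site")]

  segW <- GenomicRanges::width(proximal)
  posPos <- withSeed(seeds[1L], {
    out <- GenomicRanges::GRanges()
    while (length(out) < cfg@nPositives) {
      need <- cfg@nPositives - length(out)
      anchors <- proximal[sample.int(length(proximal),
                                     ceiling(need / 2), replace = TRUE,
                                     prob = segW)]
      aPos <- GenomicRanges::start(anchors) +
        floor(runif(length(anchors)) * GenomicRanges::width(anchors))
      clump <- lapply(seq_along(anchors), function(i) {
        k <- sample(1:3, 1L)
        unique(pmax(1L, aPos[i] + sample(-300:300, k)))
      })
      gr <- GenomicRanges::GRanges(
        rep(as.character(GenomeInfoDb::seqnames(anchors)),
            lengths(clump)),
        IRanges::IRanges(unlist(clump), width = 1L))
      gr <- gr[!IRanges::overlapsAny(gr, coding)]
      out <- suppressWarnings(c(out, gr))
      out <- out[!duplicated(paste0(GenomeInfoDb::seqnames(out), ":",
                                    GenomicRanges::start(out)))]
    }
    out[seq_len(cfg@nPositives)]
  })

  negPos <- withSeed(seeds[2L], {
    out <- GenomicRanges::GRanges()
    while (length(out) < cfg@nNegativePool) {
      need <- cfg@nNegativePool - length(out)
      nProx <- round(need * cfg@poolGeneBias)
      grp <- GenomicRanges::GRanges()
      if (nProx > 0) {
        sg <- proximal[sample.int(length(proximal), nProx, replace = TRUE,
                                  prob = segW)]
        pp <- GenomicRanges::start(sg) +
          floor(runif(nProx) * GenomicRanges::width(sg))
        grp <- GenomicRanges::GRanges(
          as.character(GenomeInfoDb::seqnames(sg)),
          IRanges::IRanges(pp, width = 1L))
      }
      ct <- sample(names(layout$contigs), need - nProx + 10L,
                   replace = TRUE)
      p <- 1L + floor(runif(length(ct)) * (layout$contigs[ct] - 1L))
      gr <- suppressWarnings(
        c(grp, GenomicRanges::GRanges(ct, IRanges::IRanges(p, width = 1L))))
      gr <- gr[!IRanges::overlapsAny(gr, coding)]
      out <- suppressWarnings(c(out, gr))
      out <- out[!duplicated(paste0(GenomeInfoDb::seqnames(out), ":",
                                    GenomicRanges::start(out)))]
    }
    out[seq_len(cfg@nNegativePool)]
  })

  all <- c(posPos, negPos)
  labels <- rep(c("positive", "negative"),
                c(length(posPos), length(negPos)))
  al <- withSeed(seeds[3L], randomAlleles(length(all)))
  variants <- makeVariants(as.character(GenomeInfoDb::seqnames(all)),
                           GenomicRanges::start(all), al$ref, al$alt,
                           label = labels)
  ## drop collisions between positive and pool positions
  dup <- duplicated(paste0(GenomeInfoDb::seqnames(variants), ":",
                           GenomicRanges::start(variants)))
  variants <- variants[!dup]
  labels <- variants$label
  X <- simulateFeatures(cfg, variants, labels, seeds[4L])
  list(variants = variants, X = X,
       truth = list(informative = cfg@informative,
                    effect_size = cfg@effectSize, labels = labels))
}

#' Materialise feature tracks for simulated variants
#'
#' Builds, for every non-computed schema feature, a 1 bp interval track
#' holding that feature's simulated value at each variant position (only
#' non-zero positions for binary features).  Annotating the variants with
#' these tracks via [annotateVariants()] reproduces the simulated matrix
#' exactly, which ties the generator to the real annotation path.
#'
#' @param variants variant `GRanges`.
#' @param X simulated feature matrix.
#' @param schema feature schema.
#' @return named list of [IntervalTrack-class].
#' @export
simulateTracks <- function(variants, X, schema = defaultFeatureSchema()) {
  agg <- featureAggregations(schema)
  dt <- featureDtypes(schema)
  ct <- as.character(GenomeInfoDb::seqnames(variants))
  pos <- GenomicRanges::start(variants)
  o <- order(ct, pos)
  tracks <- list()
  for (fn in featureNames(schema)) {
    if (agg[[fn]] == "computed") next
    keep <- if (dt[[fn]] == "binary") which(X[, fn] != 0) else seq_len(nrow(X))
    keep <- keep[order(ct[keep], pos[keep])]
    if (!length(keep)) {
      tracks[[fn]] <- intervalTrack(character(0), integer(0), integer(0),
                                    data.frame(value = numeric(0)))
      next
    }
    tracks[[fn]] <- intervalTrack(ct[keep], pos[keep], pos[keep],
                                  data.frame(value = X[keep, fn]))
  }
  tracks
}

#' Write a complete fixture directory
#'
#' Emits the formats the pipeline reads: positive and pool variants as
#' VCF, bands as BED, gene segments and region/gene pairs as TSV, one BED
#' track per feature, and the ground truth as JSON.
#'
#' @param dir output directory (created).
#' @param layout from [simulateLayout()].
#' @param sim from [simulateVariants()].
#' @param schema feature schema.
#' @param seed seed recorded in headers.
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(dir, layout, sim, schema = defaultFeatureSchema(),
                          seed = NA_integer_) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  hdr <- sprintf("regvarRF %s simulate seed=%s",
                 as.character(utils::packageVersion("regvarRF")), seed)
  v <- sim$variants
  writeVariantsVcf(v[v$label == "positive"],
                   file.path(dir, "positives.vcf"), comment = hdr)
  writeVariantsVcf(v[v$label == "negative"],
                   file.path(dir, "pool.vcf"), comment = hdr)
  b <- layout$bands
  writeLines(c(paste0("# ", hdr),
               paste(as.character(GenomeInfoDb::seqnames(b)),
                     GenomicRanges::start(b) - 1L, GenomicRanges::end(b),
                     b$band_name, sep = "\t")),
             file.path(dir, "bands.bed"))
  segs <- layout$genes@segments
  writeTsv(data.frame(contig = as.character(GenomeInfoDb::seqnames(segs)),
                      start = GenomicRanges::start(segs) - 1L,
                      end = GenomicRanges::end(segs),
                      gene_id = segs$gene_id, biotype = segs$biotype),
           file.path(dir, "gene_segments.tsv"), comment = hdr)
  tss <- layout$genes@tss
  writeTsv(data.frame(contig = as.character(GenomeInfoDb::seqnames(tss)),
                      pos = GenomicRanges::start(tss),
                      gene_id = tss$gene_id, symbol = tss$symbol),
           file.path(dir, "gene_tss.tsv"), comment = hdr)
  rp <- layout$regionPairs
  writeTsv(data.frame(contig = as.character(GenomeInfoDb::seqnames(rp)),
                      start = GenomicRanges::start(rp) - 1L,
                      end = GenomicRanges::end(rp),
                      gene_id = rp$gene_id, source = rp$source),
           file.path(dir, "regions.tsv"), comment = hdr)
  tracks <- simulateTracks(sim$variants, sim$X, schema)
  for (fn in names(tracks)) {
    tr <- tracks[[fn]]
    writeLines(paste(as.character(GenomeInfoDb::seqnames(tr@ranges)),
                     GenomicRanges::start(tr@ranges) - 1L,
                     GenomicRanges::end(tr@ranges),
                     signif(tr@values$value, 6), sep = "\t"),
               file.path(dir, "tracks", paste0(fn, ".bed")))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back
#'
#' @param dir directory written by [writeFixtures()].
#' @param schema feature schema.
#' @return list with `positives`, `pool`, `bands`, `genes`, `regionPairs`,
#'   `regions`, `tracks`, `truth`.
#' @export
readFixtures <- function(dir, schema = defaultFeatureSchema()) {
  positives <- readVariants(file.path(dir, "positives.vcf"),
                            label = "positive")
  pool <- readVariants(file.path(dir, "pool.vcf"), label = "negative")
  bands <- readBands(file.path(dir, "bands.bed"))
  segdf <- readTsv(file.path(dir, "gene_segments.tsv"))
  segs <- GenomicRanges::GRanges(segdf$contig,
                                 IRanges::IRanges(segdf$start + 1L,
                                                  segdf$end))
  segs$gene_id <- segdf$gene_id
  segs$biotype <- segdf$biotype
  tssdf <- readTsv(file.path(dir, "gene_tss.tsv"))
  tss <- GenomicRanges::GRanges(tssdf$contig,
                                IRanges::IRanges(tssdf$pos, width = 1L))
  tss$gene_id <- tssdf$gene_id
  tss$symbol <- tssdf$symbol
  rp <- readRegionTable(file.path(dir, "regions.tsv"))
  trackFiles <- list.files(file.path(dir, "tracks"), pattern = "\\.bed$",
                           full.names = TRUE)
  tracks <- lapply(trackFiles, readIntervalTable, value_columns = "value")
  names(tracks) <- sub("\\.bed$", "", basename(trackFiles))
  list(positives = positives, pool = pool, bands = bands,
       genes = geneAnnotation(segs, tss), regionPairs = rp,
       regions = mergeRegulatoryDatasets(rp),
       tracks = tracks,
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
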