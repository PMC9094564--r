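test_that("random sampling is uniform, capped, and seed-reproducible", {
  st <- sharedStudy()
  pool <- st$sim$variants[st$sim$variants$label == "negative"]
  r1 <- sampleRandom(pool, 50L, seed = 3L)
  r2 <- sampleRandom(pool, 50L, seed = 3L)
  expect_length(r1$variants, 50L)
  expect_identical(GenomicRanges::start(r1$variants),
                   GenomicRanges::start(r2$variants))
  expect_false(identical(
    GenomicRanges::start(sampleRandom(pool, 50L, seed = 4L)$variants),
    GenomicRanges::start(r1$variants)))
  expect_length(sampleRandom(pool, 0L, seed = 1L)$variants, 0L)
  small <- pool[1:10]
  rAll <- sampleRandom(small, 10L, seed = 1L)
  expect_length(rAll$variants, 10L)
  over <- sampleRandom(small, 20L, seed = 1L)
  expect_length(over$variants, 10L)
  expect_match(over$report$warnings, "pool has only")
})

test_that("local negatives all lie within the window of some positive", {
  st <- sharedStudy()
  pos <- st$sim$variants[st$sim$variants$label == "positive"]
  pool <- st$sim$variants[st$sim$variants$label == "negative"]
  loc <- sampleLocal(pool, pos, window_bp = 1000L)
  expect_gt(length(loc$variants), 0L)
  ## exhaustive distance assert
  for (ct in unique(as.character(GenomeInfoDb::seqnames(loc$variants)))) {
    np <- GenomicRanges::start(
      loc$variants[GenomeInfoDb::seqnames(loc$variants) == ct])
    pp <- GenomicRanges::start(pos[GenomeInfoDb::seqnames(pos) == ct])
    mind <- vapply(np, function(x) min(abs(pp - x)), numeric(1))
    expect_true(all(mind <= 1000))
  }
  ## dropped positives have no pool variant in range
  if (length(loc$report$dropped_positives)) {
    d <- loc$report$dropped_positives[1]
    ct <- as.character(GenomeInfoDb::seqnames(d))
    pp <- GenomicRanges::start(pool[GenomeInfoDb::seqnames(pool) == ct])
    expect_gt(min(abs(pp - GenomicRanges::start(d))), 1000)
  }
})

test_that("a zero window keeps only exact-position negatives", {
  pos <- makeVariants("chr1", c(5000), "A", "G", label = "positive")
  pool <- makeVariants("chr1", c(4200, 5000, 5800, 6500), "C", "T",
                       label = "negative")
  loc <- sampleLocal(pool, pos, window_bp = 0L)
  expect_equal(GenomicRanges::start(loc$variants), 5000L)
  loc2 <- sampleLocal(pool, pos, window_bp = 1000L)
  expect_equal(GenomicRanges::start(loc2$variants), c(4200L, 5000L, 5800L))
})

test_that("adjusted sampling restricts to positive-bearing bands and
          matches biotype proportions", {
  st <- sharedStudy()
  pos <- st$sim$variants[st$sim$variants$label == "positive"]
  pool <- st$sim$variants[st$sim$variants$label == "negative"]
  bands <- st$layout$bands
  genes <- st$layout$genes
  adj <- sampleAdjusted(pool, pos, bands, genes, n_total = 600L, seed = 9L)
  neg <- adj$variants
  expect_equal(length(neg), 600L)
  ## (a) band contract
  posBands <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(pos, bands)))
  negBands <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(neg, bands)))
  expect_true(all(negBands %in% posBands))
  ## (b) biotype proportions within tolerance when no stratum exhausted
  expect_length(adj$report$warnings, 0L)
  pb <- adj$report$per_biotype
  expect_true(all(abs(pb$positive_fraction - pb$negative_fraction) <=
                    0.01 + 1e-9))
  ## (c) deterministic
  adj2 <- sampleAdjusted(pool, pos, bands, genes, n_total = 600L, seed = 9L)
  expect_identical(GenomicRanges::start(adj$variants),
                   GenomicRanges::start(adj2$variants))
  expect_length(sampleAdjusted(pool, pos, bands, genes, 0L, 1L)$variants, 0L)
})

test_that("exhausted strata under-fill with a warning and flag positives", {
  pos <- makeVariants("chr1", c(1500, 2500), "A", "G", label = "positive")
  pool <- makeVariants("chr1", c(1600, 9000, 9100, 9200), "C", "T",
                       label = "negative")
  bands <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  bands$band_name <- "q1"
  segs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000))
  segs$gene_id <- "G1"
  segs$biotype <- "promoter"
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3000, 3000))
  tss$gene_id <- "G1"; tss$symbol <- "G1"
  genes <- geneAnnotation(segs, tss)
  ## both positives are promoter; only one promoter negative exists
  adj <- sampleAdjusted(pool, pos, bands, genes, n_total = 4L, seed = 1L)
  expect_match(adj$report$warnings, "promoter.*exhausted")
  expect_equal(length(adj$report$dropped_positives), 2L)
  expect_lt(length(adj$variants), 4L)
})

test_that("per-tree balanced samples have exactly equal class counts", {
  y <- rep(c("positive", "negative"), c(7L, 31L))
  s <- balancedTreeSamples(y, n_trees = 25L, seed = 2L)
  expect_length(s, 25L)
  for (ix in s) {
    expect_length(ix, 14L)
    expect_equal(sum(y[ix] == "positive"), 7L)
    expect_equal(sum(y[ix] == "negative"), 7L)
  }
  ## independent across trees, reproducible across runs
  expect_identical(s, balancedTreeSamples(y, 25L, seed = 2L))
  expect_false(identical(s[[1]], s[[2]]))
  expect_error(balancedTreeSamples(rep("positive", 5), 3L, 1L),
               "two classes")
})
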