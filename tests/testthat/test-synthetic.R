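test_that("bands tile contigs exactly and layouts are seed-stable", {
  st <- sharedStudy()
  lay <- st$layout
  for (ct in names(lay$contigs)) {
    b <- lay$bands[GenomeInfoDb::seqnames(lay$bands) == ct]
    expect_equal(sum(GenomicRanges::width(b)), unname(lay$contigs[[ct]]))
    expect_equal(min(GenomicRanges::start(b)), 1L)
    ## non-overlapping, gap-free tiling
    o <- order(GenomicRanges::start(b))
    expect_equal(GenomicRanges::start(b)[o][-1],
                 head(GenomicRanges::end(b)[o], -1) + 1L)
  }
  ## every region target exists in the gene set
  expect_true(all(unlist(lay$regions$target_genes) %in%
                    lay$genes@tss$gene_id))
  ## same seed, same layout
  lay2 <- simulateLayout(st$cfg)
  expect_identical(GenomicRanges::start(lay2$genes@segments),
                   GenomicRanges::start(lay$genes@segments))
  expect_identical(as.list(lay2$regions$target_genes),
                   as.list(lay$regions$target_genes))
})

test_that("impossible geometries are refused", {
  cfg <- simulationConfig(nContigs = 1L, contigLength = 100000L,
                          nGenes = 50L, nPositives = 10L,
                          nNegativePool = 100L)
  expect_error(simulateLayout(cfg), "geometry impossible")
})

test_that("simulated variants are reproducible and class-structured", {
  st <- sharedStudy()
  sim2 <- simulateVariants(st$cfg, st$layout)
  expect_identical(GenomicRanges::start(sim2$variants),
                   GenomicRanges::start(st$sim$variants))
  expect_identical(sim2$X, st$sim$X)
  ## biotype composition differs between classes (the location bias that
  ## motivates adjusted sampling)
  bt <- assignBiotype(st$sim$variants, st$layout$genes)
  lab <- st$sim$variants$label
  fracPos <- prop.table(table(bt[lab == "positive"]))
  fracNeg <- prop.table(table(bt[lab == "negative"]))
  expect_gt(max(abs(fracPos - fracNeg)), 0.1)
  ## no variant in CDS or splice site; all positions distinct
  expect_false(any(bt %in% c("CDS", "splice_site")))
  expect_equal(anyDuplicated(paste0(
    GenomeInfoDb::seqnames(st$sim$variants), ":",
    GenomicRanges::start(st$sim$variants))), 0L)
  ## informative features separate the classes at the configured d
  for (fn in st$cfg@informative) {
    d <- cohensD(st$sim$X[lab == "positive", fn],
                 st$sim$X[lab == "negative", fn])
    expect_equal(d, st$cfg@effectSize, tolerance = 0.15)
  }
})

test_that("a zero effect size yields chance-level discrimination", {
  cfg <- simulationConfig(nPositives = 100L, nNegativePool = 400L,
                          nGenes = 40L, nRegions = 50L, effectSize = 0,
                          autocorWeight = 0, seed = 23L)
  lay <- simulateLayout(cfg)
  sim <- simulateVariants(cfg, lay)
  fold <- stratifiedFolds(sim$variants$label, k = 4L, seed = 1L)
  cv <- crossValidate(sim$X, sim$variants$label, fold,
                      defaultFeatureSchema(),
                      forestParams(n_trees = 60L, seed = 2L))
  expect_gt(cv$roc_auc, 0.35)
  expect_lt(cv$roc_auc, 0.65)
})

test_that("fixtures round-trip through the package readers", {
  cfg <- simulationConfig(nPositives = 40L, nNegativePool = 300L,
                          nGenes = 30L, nRegions = 40L, seed = 31L)
  lay <- simulateLayout(cfg)
  sim <- simulateVariants(cfg, lay)
  dir <- file.path(tempdir(), "fx-roundtrip")
  unlink(dir, recursive = TRUE)
  writeFixtures(dir, lay, sim, seed = 31L)
  fx <- readFixtures(dir)
  ## variants round-trip exactly, positives first
  pos <- sim$variants[sim$variants$label == "positive"]
  expect_equal(GenomicRanges::start(fx$positives),
               GenomicRanges::start(pos))
  expect_equal(fx$positives$ref, pos$ref)
  expect_equal(length(fx$pool), sum(sim$variants$label == "negative"))
  ## bands and regions round-trip
  expect_equal(GenomicRanges::start(fx$bands),
               GenomicRanges::start(lay$bands))
  expect_equal(length(fx$regions), length(lay$regions))
  ## annotating the read-back variants with the read-back tracks
  ## reproduces the simulated feature matrix (to write precision)
  vars <- c(fx$positives, fx$pool)
  X2 <- annotateVariants(vars, fx$tracks)
  key <- variantKeyOf(sim$variants)
  Xref <- sim$X[match(variantKeyOf(vars), key), ]
  expect_equal(unname(X2), unname(Xref), tolerance = 1e-5)
  expect_equal(fx$truth$informative, cfg@informative)
})
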