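regionPairs <- function(contig, start, end, gene, source) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  gr$gene_id <- gene
  gr$source <- source
  gr
}

test_that("overlapping regions merge with unioned targets and sources", {
  rp <- c(regionPairs("chr1", 101, 200, "geneA", "src1"),
          regionPairs("chr1", 151, 250, "geneB", "src2"))
  m <- mergeRegulatoryDatasets(rp)
  expect_length(m, 1L)
  expect_equal(GenomicRanges::start(m), 101L)
  expect_equal(GenomicRanges::end(m), 250L)
  expect_setequal(unlist(m$target_genes), c("geneA", "geneB"))
  expect_setequal(unlist(m$sources), c("src1", "src2"))
  ## disjoint regions stay apart; adjacency without a shared base does not
  ## merge
  rp2 <- c(regionPairs("chr1", 1, 100, "g1", "s"),
           regionPairs("chr1", 101, 200, "g2", "s"))
  expect_length(mergeRegulatoryDatasets(rp2), 2L)
})

test_that("chained overlaps merge transitively (interval-sweep oracle)", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 30L
    st <- sample(1:2000, n)
    en <- st + sample(50:400, n, replace = TRUE)
    rp <- regionPairs("chr1", st, en, paste0("g", 1:n),
                      sample(c("s1", "s2", "s3"), n, replace = TRUE))
    m <- mergeRegulatoryDatasets(rp)
    ## oracle: sweep sorted intervals, extend while next start <= cur end
    o <- order(st)
    comp <- list(); cs <- st[o][1]; ce <- en[o][1]
    for (i in seq_len(n - 1L) + 1L) {
      if (st[o][i] <= ce) ce <- max(ce, en[o][i])
      else { comp[[length(comp) + 1L]] <- c(cs, ce); cs <- st[o][i]; ce <- en[o][i] }
    }
    comp[[length(comp) + 1L]] <- c(cs, ce)
    expect_equal(GenomicRanges::start(m), vapply(comp, `[`, 0, 1))
    expect_equal(GenomicRanges::end(m), vapply(comp, `[`, 0, 2))
    ## idempotence: re-merging the merged output changes nothing
    flat <- unlist(lapply(seq_along(m), function(i)
      lapply(unlist(m$target_genes[i]), function(g) {
        gr <- GenomicRanges::granges(m[i]); gr$gene_id <- g
        gr$source <- unlist(m$sources[i])[1]; gr
      })))
    m2 <- mergeRegulatoryDatasets(do.call(c, flat))
    expect_equal(GenomicRanges::start(m2), GenomicRanges::start(m))
    expect_equal(GenomicRanges::end(m2), GenomicRanges::end(m))
    expect_equal(lapply(m2$target_genes, sort),
                 lapply(m$target_genes, sort))
  }
})

test_that("passthrough resources are kept unmerged", {
  rp <- c(regionPairs("chr1", 101, 200, "geneA", "src1"),
          regionPairs("chr1", 151, 250, "geneB", "special"))
  m <- mergeRegulatoryDatasets(rp, passthrough = "special")
  expect_length(m, 2L)
  expect_true(any(vapply(m$sources, function(s)
    identical(s, "special"), logical(1))))
})

test_that("disease-gene filtering keeps only matching regions and ranks
          deterministically", {
  regions <- mergeRegulatoryDatasets(
    regionPairs(c("chr1", "chr1", "chr2"), c(100, 500, 100),
                c(200, 600, 200), c("DISEASE1", "other", "DISEASE1"), "s"))
  scored <- data.frame(
    contig = c("chr1", "chr1", "chr2", "chr1"),
    pos = c(150L, 550L, 150L, 190L),
    ref = "A", alt = "G",
    score = c(0.9, 0.95, 0.9, 0.2))
  r <- filterByDiseaseGenes(scored, regions, "DISEASE1")
  ## the variant in the non-matching region is dropped
  expect_equal(nrow(r), 3L)
  expect_true(all(grepl("DISEASE1", r$matched_genes)))
  expect_equal(r$rank, 1:3)
  ## equal scores: lower coordinate (chr1:150 < chr2:150) ranks first
  expect_equal(r$contig[1:2], c("chr1", "chr2"))
  expect_true(all(diff(r$score) <= 0))
  ## empty gene set errors; no overlap returns empty
  expect_error(filterByDiseaseGenes(scored, regions, character(0)),
               "empty")
  none <- filterByDiseaseGenes(scored, regions, "UNRELATED")
  expect_equal(nrow(none), 0L)
  ## filtering never widens the candidate set
  expect_lte(nrow(r), nrow(scored))
})

test_that("spike-in benchmark ranks seeded pathogenic variants", {
  sch <- tinySchema(2L)
  td <- tinyData(n = 400L, p = 2L, shift = 4, seed = 19L)
  m <- trainForest(td$X, td$y, sch, forestParams(n_trees = 50L, seed = 1L))
  regions <- mergeRegulatoryDatasets(
    regionPairs("chr1", 1000L * (1:40) + 1L, 1000L * (1:40) + 500L,
                rep(c("gA", "gB"), 20), "s"))
  set.seed(20)
  bgPos <- 1000L * (3:40) + 100L
  background <- makeVariants("chr1", bgPos, "A", "G", label = "negative")
  backgroundX <- matrix(rnorm(length(bgPos) * 2), ncol = 2,
                        dimnames = list(NULL, c("f1", "f2")))
  spikes <- makeVariants("chr1", c(1100L, 2100L, 999999L), "C", "T",
                         label = "positive")
  spikeX <- cbind(f1 = rnorm(3, 4), f2 = rnorm(3))
  res <- spikeInBenchmark(background, backgroundX, spikes, spikeX,
                          list("gA", "gB", "gA"), m, regions)
  expect_equal(nrow(res), 3L)
  ## strongly positive-like spike-ins in matching regions rank first
  expect_equal(res$rank[1], 1L)
  expect_equal(res$rank[2], 1L)
  ## a spike-in outside every region is unrankable, not ranked
  expect_true(res$unrankable[3])
  expect_true(is.na(res$rank[3]))
  expect_true(all(res$candidate_set_size[1:2] > 1))
  ## spike-ins colliding with background keys are refused
  expect_error(
    spikeInBenchmark(background, backgroundX, background[1], spikeX[1, ,
                     drop = FALSE], list("gA"), m, regions),
    "absent from the background")
})
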