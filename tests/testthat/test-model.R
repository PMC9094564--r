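test_that("a separable problem is fit perfectly and reproducibly", {
  td <- tinyData(n = 120L, p = 2L, shift = 6, seed = 3L)
  sch <- tinySchema(2L)
  m1 <- trainForest(td$X, td$y, sch, forestParams(n_trees = 40L, seed = 7L))
  s <- scoreMatrix(m1, td$X)
  expect_equal(rocAuc(s, td$y), 1.0)
  expect_true(all(s >= 0 & s <= 1))
  ## node-by-node determinism
  m2 <- trainForest(td$X, td$y, sch, forestParams(n_trees = 40L, seed = 7L))
  expect_identical(m1@trees, m2@trees)
  expect_identical(m1@inbag, m2@inbag)
  m3 <- trainForest(td$X, td$y, sch, forestParams(n_trees = 40L, seed = 8L))
  expect_false(identical(m1@trees, m3@trees))
})

test_that("engine prediction and path routing agree exactly", {
  fx <- sharedModel()
  s1 <- scoreMatrix(fx$model, fx$X, useEngine = TRUE)
  s2 <- scoreMatrix(fx$model, fx$X, useEngine = FALSE)
  expect_equal(s1, s2, tolerance = 1e-12)
  ## ensemble score is the mean of per-tree scores
  half1 <- scoreMatrix(fx$model, fx$X[1:20, ], trees = 1:75)
  half2 <- scoreMatrix(fx$model, fx$X[1:20, ], trees = 76:150)
  expect_equal((half1 + half2) / 2, s1[1:20], tolerance = 1e-12)
})

test_that("shuffled labels give chance-level cross-validation", {
  td <- tinyData(n = 200L, p = 4L, shift = 2, seed = 5L)
  yShuf <- withr::with_seed(9L, sample(td$y))
  fold <- stratifiedFolds(yShuf, k = 4L, seed = 2L)
  cv <- crossValidate(td$X, yShuf, fold, tinySchema(4L),
                      forestParams(n_trees = 60L, seed = 1L))
  expect_gt(cv$roc_auc, 0.35)
  expect_lt(cv$roc_auc, 0.65)
})

test_that("schema mismatches are refused", {
  fx <- sharedModel()
  expect_error(scoreMatrix(fx$model, fx$X[, 1:5]), "41 features")
  Xbad <- fx$X
  colnames(Xbad) <- rev(colnames(Xbad))
  expect_error(scoreMatrix(fx$model, Xbad), "feature order")
})

test_that("indel scoring enumerates affected plus flanking positions", {
  fx <- sharedModel()
  st <- sharedStudy()
  tracks <- simulateTracks(st$sim$variants, st$sim$X)
  ## 2-bp deletion: 4 positions x 2 substitution classes = 8 scores
  del <- makeVariants("chr1", 5000L, "ATT", "A")
  rec <- scoreIndel(fx$model, del, tracks)
  expect_equal(nrow(rec$evaluated_positions), 8L)
  expect_setequal(unique(rec$evaluated_positions$position),
                  c(5000L, 5001L, 5002L, 5003L))
  expect_equal(rec$score, max(rec$evaluated_positions$score))
  ## 1-bp insertion: 3 positions x 2 classes = 6 scores
  ins <- makeVariants("chr1", 5000L, "A", "AT")
  rec2 <- scoreIndel(fx$model, ins, tracks)
  expect_equal(nrow(rec2$evaluated_positions), 6L)
  expect_setequal(unique(rec2$evaluated_positions$position),
                  c(4999L, 5000L, 5001L))
  expect_error(scoreIndel(fx$model, makeVariants("chr1", 1, "A", "G"),
                          tracks), "not an indel")
  ## scoreVariants dispatches SNVs and indels together
  mix <- c(makeVariants("chr1", 123456L, "A", "G"), del)
  res <- scoreVariants(fx$model, mix, tracks)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$score >= 0 & res$score <= 1))
})

test_that("precomputed tables hold two predictions per position", {
  fx <- sharedModel()
  st <- sharedStudy()
  tracks <- simulateTracks(st$sim$variants, st$sim$X)
  tab <- precomputeScores(fx$model, "chr1", 5000L, 5009L, tracks)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$pos, 5000:5009)
  expect_true(all(tab$score_transition >= 0 & tab$score_transition <= 1))
  expect_true(all(tab$score_transversion >= 0 &
                    tab$score_transversion <= 1))
  ## an indel's evaluated positions agree with the precomputed table
  del <- makeVariants("chr1", 5001L, "AT", "A")
  rec <- scoreIndel(fx$model, del, tracks)
  for (i in seq_len(nrow(rec$evaluated_positions))) {
    r <- rec$evaluated_positions[i, ]
    col <- paste0("score_", r$substitution_class)
    expect_equal(r$score, tab[tab$pos == r$position, col][[1]],
                 tolerance = 1e-12)
  }
})

test_that("feature importance is normalised and ranks signal over noise", {
  td <- tinyData(n = 200L, p = 6L, shift = 3, seed = 11L)
  m <- trainForest(td$X, td$y, tinySchema(6L),
                   forestParams(n_trees = 80L, seed = 2L))
  imp <- featureImportance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_equal(names(which.max(imp)), "f1")
  expect_true(all(imp[["f1"]] > imp[-1]))
})

test_that("models survive a save/load cycle without the engine", {
  fx <- sharedModel()
  path <- tempfile(fileext = ".rds")
  saveModel(fx$model, path)
  m2 <- readModel(path)
  expect_null(m2@engine)
  expect_identical(m2@trees, fx$model@trees)
  s1 <- scoreMatrix(fx$model, fx$X[1:30, ], useEngine = FALSE)
  expect_equal(scoreMatrix(m2, fx$X[1:30, ]), s1, tolerance = 1e-12)
  expect_error(suppressWarnings(readModel(tempfile())))
})
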