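## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## A moderate simulated study reused by several test files.
sharedStudy <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- simulationConfig(nPositives = 150L, nNegativePool = 4000L,
                            nGenes = 80L, nRegions = 150L, seed = 42L)
    layout <- simulateLayout(cfg)
    sim <- simulateVariants(cfg, layout)
    .fixtures$study <- list(cfg = cfg, layout = layout, sim = sim)
  }
  .fixtures$study
}

## Training set (positives + adjusted negatives) and model on the shared
## study.
sharedModel <- function() {
  if (is.null(.fixtures$model)) {
    st <- sharedStudy()
    pos <- st$sim$variants[st$sim$variants$label == "positive"]
    pool <- st$sim$variants[st$sim$variants$label == "negative"]
    adj <- sampleAdjusted(pool, pos, st$layout$bands, st$layout$genes,
                          n_total = 600L, seed = 11L)
    vars <- c(pos, adj$variants)
    key <- variantKeyOf(st$sim$variants)
    X <- st$sim$X[match(variantKeyOf(vars), key), ]
    y <- vars$label
    model <- trainForest(X, y, defaultFeatureSchema(),
                         forestParams(n_trees = 150L, seed = 5L))
    .fixtures$model <- list(vars = vars, X = X, y = y, model = model,
                            pos = pos, pool = pool, adj = adj)
  }
  .fixtures$model
}

variantKeyOf <- function(v) {
  paste0(as.character(GenomeInfoDb::seqnames(v)), ":",
         GenomicRanges::start(v), ":", v$ref, ">", v$alt)
}

## A p-feature continuous schema for small hand-built examples.
tinySchema <- function(p, dtype = "continuous") {
  FeatureSchema(data.frame(
    name = paste0("f", seq_len(p)), group = "conservation",
    dtype = dtype, aggregation = "value", missing_value = 0))
}

## Random two-class training data with one informative feature.
tinyData <- function(n = 60L, p = 3L, shift = 2, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(c("positive", "negative"), length.out = n)
    X[y == "positive", 1L] <- X[y == "positive", 1L] + shift
    list(X = X, y = y)
  })
}

## Hand-built single-stump model: root splits f1 at 0, leaves 0.2 / 0.8.
stumpModel <- function() {
  tree <- list(left = c(2L, NA, NA), right = c(3L, NA, NA),
               var = c(1L, NA, NA), split = c(0, NA, NA),
               terminal = c(FALSE, TRUE, TRUE),
               value = c(0.5, 0.2, 0.8))
  methods::new("RegForestModel", trees = list(tree),
               inbag = list(rep(1L, 10L)), schema = tinySchema(2L),
               params = forestParams(n_trees = 1L, seed = 1L),
               threshold = 0.5,
               classLevels = c("negative", "positive"),
               nTraining = 10L, engine = NULL)
}
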