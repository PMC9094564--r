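## Independent brute-force oracle for decision-path contributions: for one
## tree, enumerate every root-to-leaf path with its split conditions and
## per-feature value deltas; a vector's contribution is the delta sum of
## the unique path whose conditions it satisfies.  Kept deliberately
## separate from the package's level-wise routing.

enumeratePaths <- function(tree) {
  paths <- list()
  walk <- function(node, conds, deltas) {
    if (tree$terminal[node]) {
      paths[[length(paths) + 1L]] <<- list(conds = conds, deltas = deltas,
                                           leaf = tree$value[node])
      return()
    }
    for (side in c("left", "right")) {
      child <- tree[[side]][node]
      d <- list(var = tree$var[node],
                delta = tree$value[child] - tree$value[node])
      cnd <- list(var = tree$var[node], split = tree$split[node],
                  left = side == "left")
      walk(child, c(conds, list(cnd)), c(deltas, list(d)))
    }
  }
  walk(1L, list(), list())
  paths
}

oracleContributions <- function(model, x) {
  p <- nFeatures(featureSchema(model))
  contrib <- numeric(p)
  bias <- 0
  score <- 0
  for (tree in model@trees) {
    paths <- enumeratePaths(tree)
    hit <- Filter(function(pt)
      all(vapply(pt$conds, function(cn)
        if (cn$left) x[cn$var] <= cn$split else x[cn$var] > cn$split,
        logical(1))), paths)
    stopifnot(length(hit) == 1L)
    pt <- hit[[1L]]
    for (d in pt$deltas) contrib[d$var] <- contrib[d$var] + d$delta
    bias <- bias + tree$value[1L]
    score <- score + pt$leaf
  }
  n <- length(model@trees)
  list(bias = bias / n, contributions = contrib / n, score = score / n)
}
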