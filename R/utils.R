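#' @import methods
#' @importFrom stats median rnorm rpois rbinom runif sd kmeans quantile ecdf
#' @importFrom utils head tail write.table read.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `expr`, and restores the previous RNG state on exit.  All stochastic
#' operations in the package route their randomness through this helper so
#' that a single integer seed makes a whole run reproducible without
#' clobbering the user's RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds from one master seed, so that independent
## components (layout, variants, per-fold forests, ...) do not share draws.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Strip any "chr" prefix from contig names
#'
#' Inputs routinely mix "chr1" and "1" dialects; all internal matching is done
#' on the stripped form while original spellings are preserved for output.
#'
#' @param x character vector of contig names.
#' @return character vector without the `chr` prefix.
#' @export
normalizeContig <- function(x) sub("^chr", "", as.character(x))

#' Stable per-variant identity key
#'
#' `contig:pos:ref>alt` with the contig's `chr` prefix stripped; used for
#' matching variants across sets and for deterministic tie-breaking.
#'
#' @param variants a variant `GRanges` (see [makeVariants()]).
#' @return character vector of keys.
#' @export
variantKey <- function(variants) {
  paste0(normalizeContig(GenomeInfoDb::seqnames(variants)), ":",
         GenomicRanges::start(variants), ":",
         variants$ref, ">", variants$alt)
}

## TSV writer used by all tabular outputs: header line, no quoting, 6
## significant digits for floats.
writeTsv <- function(df, path, comment = NULL) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  as.data.frame(data.table::fread(text = paste(ln, collapse = "\n"),
                                  sep = "\t", header = TRUE))
}
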