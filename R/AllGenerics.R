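#' @include AllClasses.R
NULL

#' Accessors for FeatureSchema
#'
#' @param x a [FeatureSchema-class].
#' @return `featureNames` returns the ordered feature names;
#'   `featureGroups`, `featureDtypes`, `featureAggregations` and
#'   `missingValues` the corresponding per-feature vectors, named by
#'   feature; `nFeatures` the number of features.
#' @name schema-accessors
#' @aliases featureNames featureGroups featureDtypes featureAggregations
#'   missingValues nFeatures
NULL

#' @rdname schema-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname schema-accessors
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))
#' @rdname schema-accessors
#' @export
setGeneric("featureDtypes", function(x) standardGeneric("featureDtypes"))
#' @rdname schema-accessors
#' @export
setGeneric("featureAggregations",
           function(x) standardGeneric("featureAggregations"))
#' @rdname schema-accessors
#' @export
setGeneric("missingValues", function(x) standardGeneric("missingValues"))
#' @rdname schema-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname schema-accessors
setMethod("featureNames", "FeatureSchema", function(x) x@features$name)
#' @rdname schema-accessors
setMethod("featureGroups", "FeatureSchema", function(x)
  stats::setNames(x@features$group, x@features$name))
#' @rdname schema-accessors
setMethod("featureDtypes", "FeatureSchema", function(x)
  stats::setNames(x@features$dtype, x@features$name))
#' @rdname schema-accessors
setMethod("featureAggregations", "FeatureSchema", function(x)
  stats::setNames(x@features$aggregation, x@features$name))
#' @rdname schema-accessors
setMethod("missingValues", "FeatureSchema", function(x)
  stats::setNames(x@features$missing_value, x@features$name))
#' @rdname schema-accessors
setMethod("nFeatures", "FeatureSchema", function(x) nrow(x@features))

setMethod("show", "FeatureSchema", function(object) {
  g <- table(object@features$group)
  cat("FeatureSchema with", nrow(object@features), "features\n")
  for (n in names(g)) cat(" ", n, ":", g[[n]], "\n")
})

#' Accessors for RegForestModel
#'
#' @param x a [RegForestModel-class].
#' @return `nTrees` the number of trees; `featureSchema` the schema the
#'   model was trained on; `decisionThreshold` the score threshold used to
#'   call a variant regulatory; `treeSamples` the per-tree balanced training
#'   multisets (inbag counts per training row); `classLevels` the class
#'   labels (negative first).
#' @name model-accessors
#' @aliases nTrees featureSchema decisionThreshold treeSamples classLevels
NULL

#' @rdname model-accessors
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))
#' @rdname model-accessors
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))
#' @rdname model-accessors
#' @export
setGeneric("decisionThreshold",
           function(x) standardGeneric("decisionThreshold"))
#' @rdname model-accessors
#' @export
setGeneric("decisionThreshold<-",
           function(x, value) standardGeneric("decisionThreshold<-"))
#' @rdname model-accessors
#' @export
setGeneric("treeSamples", function(x) standardGeneric("treeSamples"))
#' @rdname model-accessors
#' @export
setGeneric("classLevels", function(x) standardGeneric("classLevels"))

#' @rdname model-accessors
setMethod("nTrees", "RegForestModel", function(x) length(x@trees))
#' @rdname model-accessors
setMethod("featureSchema", "RegForestModel", function(x) x@schema)
#' @rdname model-accessors
setMethod("decisionThreshold", "RegForestModel", function(x) x@threshold)
#' @rdname model-accessors
setMethod("decisionThreshold<-", "RegForestModel", function(x, value) {
  x@threshold <- value
  validObject(x)
  x
})
#' @rdname model-accessors
setMethod("treeSamples", "RegForestModel", function(x) x@inbag)
#' @rdname model-accessors
setMethod("classLevels", "RegForestModel", function(x) x@classLevels)

setMethod("show", "RegForestModel", function(object) {
  cat("RegForestModel:", length(object@trees), "trees,",
      nFeatures(object@schema), "features,",
      object@nTraining, "training rows\n")
  cat("  classes:", paste(object@classLevels, collapse = " / "),
      " threshold:", object@threshold, "\n")
  cat("  params: max_depth =", object@params$max_depth,
      ", min_samples_leaf =", object@params$min_samples_leaf,
      ", mtry =", object@params$mtry %||% "sqrt(p)", "\n")
})

setMethod("show", "IntervalTrack", function(object) {
  cat("IntervalTrack:", length(object@ranges), "intervals,",
      ncol(object@values), "value column(s):",
      paste(names(object@values), collapse = ", "), "\n")
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", length(object@tss), "genes,",
      length(object@segments), "biotype segments\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nContigs, "contig(s) x",
      object@contigLength, "bp,", object@nGenes, "genes,",
      object@nRegions, "regions\n")
  cat("  variants:", object@nPositives, "positives /",
      object@nNegativePool, "negative pool;",
      length(object@informative), "informative features at d =",
      object@effectSize, "\n")
})
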