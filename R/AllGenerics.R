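#' @include AllClasses.R
NULL

#' Feature names of a table or selection
#' @param x a FeatureTable, FeatureRanking or SelectionResult.
#' @return character vector of feature names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Binary class labels of a FeatureTable
#' @param x a FeatureTable.
#' @return integer 0/1 vector, one entry per sample.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Sample identifiers of a FeatureTable
#' @param x a FeatureTable.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Samples x features matrix of a FeatureTable
#' @param x a FeatureTable.
#' @return numeric matrix with samples in rows, features in columns.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Soft-voting class probabilities
#' @param object an EnsembleModel or ClassifierFit.
#' @param newdata samples x features matrix (raw, unnormalized descriptor
#'   values for ensembles; already-normalized member features for fits).
#' @return numeric matrix with columns `p0`, `p1`.
#' @export
setGeneric("predictProba", function(object, newdata) standardGeneric("predictProba"))

#' Hard class prediction (1 = DNA-binding)
#' @inheritParams predictProba
#' @return integer 0/1 vector.
#' @export
setGeneric("predictClass", function(object, newdata) standardGeneric("predictClass"))

#' Accuracy-proportional weights of an ensemble
#' @param object an EnsembleModel.
#' @return numeric weight vector summing to 1.
#' @export
setGeneric("ensembleWeights", function(object) standardGeneric("ensembleWeights"))

#' @export
#' @rdname featureNames
setMethod("featureNames", "FeatureTable", function(x) rownames(x))

#' @export
#' @rdname featureNames
setMethod("featureNames", "FeatureRanking", function(x) x@orderedNames)

#' @export
#' @rdname featureNames
setMethod("featureNames", "SelectionResult", function(x) x@selectedNames)

#' @export
#' @rdname classLabels
setMethod("classLabels", "FeatureTable", function(x)
  as.integer(SummarizedExperiment::colData(x)$label))

#' @export
#' @rdname sampleIds
setMethod("sampleIds", "FeatureTable", function(x) colnames(x))

#' @export
#' @rdname featureMatrix
setMethod("featureMatrix", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

setMethod("show", "ResidueMatrix", function(object) {
  cat("ResidueMatrix '", object@proteinId, "' (", object@sourceKind, "): ",
      nrow(object@values), " x ", ncol(object@values),
      if (object@normalized) ", sigmoid-normalized" else ", raw", "\n", sep = "")
})

setMethod("dim", "ResidueMatrix", function(x) dim(x@values))

setMethod("show", "FeatureTable", function(object) {
  lab <- classLabels(object)
  cat("FeatureTable: ", ncol(object), " proteins x ", nrow(object),
      " features (", sum(lab == 1L), " positive / ", sum(lab == 0L),
      " negative)\n", sep = "")
})

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (", object@method, "): ", length(object@orderedNames),
      " features; top: ",
      paste(utils::head(object@orderedNames, 3), collapse = ", "), "\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult '", object@origin, "': ", length(object@selectedNames),
      " features\n", sep = "")
})

setMethod("show", "MetricSet", function(object) {
  cat(sprintf("MetricSet: ACC %.4f  MCC %.4f  SN %.4f  SP %.4f\n",
              object@ACC, object@MCC, object@SN, object@SP))
  cat("counts:", paste(names(object@counts), object@counts, collapse = " "), "\n")
})

setMethod("show", "CVReport", function(object) {
  cat("CVReport (", object@classifier, ", ", length(object@folds),
      "-fold, seed ", object@seed, ")\n", sep = "")
  show(object@pooled)
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel with", length(object@members), "members\n")
  if (length(object@members)) {
    org <- vapply(object@members, function(m) m@origin, character(1))
    acc <- vapply(object@members, function(m) m@cvAcc, numeric(1))
    utils::head(data.frame(origin = org, cvAcc = acc,
                           weight = object@weights), 8) |> print()
    if (length(org) > 8) cat("...\n")
  }
})

#' @export
#' @rdname ensembleWeights
setMethod("ensembleWeights", "EnsembleModel", function(object) object@weights)
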