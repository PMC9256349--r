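#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ResidueMatrix: an L x d residue-level representation bound to one protein
#'
#' Holds either a position-specific scoring matrix (d = 20 substitution
#' log-odds per residue) or a per-residue embedding (e.g. d = 1280 for a
#' transformer protein language model), before or after sigmoid
#' normalization.
#'
#' @slot proteinId single identifier string.
#' @slot sourceKind `"pssm"` or `"embedding"`.
#' @slot values numeric matrix, one row per residue.
#' @slot normalized `TRUE` after [sigmoidNormalize()] has been applied.
#'
#' @exportClass ResidueMatrix
setClass("ResidueMatrix",
  representation(proteinId = "character", sourceKind = "character",
                 values = "matrix", normalized = "logical"))

setValidity("ResidueMatrix", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be a single string")
  if (!object@sourceKind %in% c("pssm", "embedding"))
    msg <- c(msg, "sourceKind must be 'pssm' or 'embedding'")
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    msg <- c(msg, "values must have at least one row and one column")
  if (anyNA(object@values)) msg <- c(msg, "values must not contain NA")
  if (isTRUE(object@normalized)) {
    rng <- range(object@values)
    # sigmoid maps into the open unit interval; doubles saturate at 0/1
    if (rng[1] < 0 || rng[2] > 1)
      msg <- c(msg, "normalized values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ResidueMatrix
#'
#' @param values numeric L x d matrix of residue-level scores.
#' @param proteinId identifier of the protein the rows belong to.
#' @param sourceKind `"pssm"` or `"embedding"`.
#' @param normalized whether `values` are already sigmoid-normalized.
#' @return A [ResidueMatrix-class] object.
#' @examples
#' m <- ResidueMatrix(matrix(rnorm(40), 2, 20), "p1", "pssm")
#' dim(m)
#' @export
ResidueMatrix <- function(values, proteinId, sourceKind = c("embedding", "pssm"),
                          normalized = FALSE) {
  sourceKind <- match.arg(sourceKind)
  new("ResidueMatrix", proteinId = as.character(proteinId),
      sourceKind = sourceKind, values = as.matrix(values),
      normalized = isTRUE(normalized))
}

#' FeatureTable: samples x features descriptors with binary labels
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with features as rows
#' and proteins as columns; the `label` column of `colData` holds the binary
#' class (1 = DNA-binding, 0 = non-binding).
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'label' column")
  } else {
    lab <- cd$label
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1 without NA")
  }
  fn <- rownames(object)
  if (is.null(fn) || anyDuplicated(fn) || any(fn == ""))
    msg <- c(msg, "feature names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, samples in rows, features in columns (the
#'   orientation ranking/CV code consumes); stored transposed internally.
#' @param labels binary vector (1 = DNA-binding), one entry per sample.
#' @param ids sample identifiers; defaults to `rownames(values)`.
#' @return A [FeatureTable-class] object.
#' @examples
#' ft <- FeatureTable(matrix(runif(20), 4, 5,
#'                    dimnames = list(NULL, paste0("f", 1:5))),
#'                    labels = c(0, 0, 1, 1))
#' ft
#' @export
FeatureTable <- function(values, labels, ids = rownames(values)) {
  values <- as.matrix(values)
  if (length(labels) != nrow(values))
    stop("label length (", length(labels), ") does not match sample count (",
         nrow(values), ")")
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feat", seq_len(ncol(values)))
  assay <- t(values)
  colnames(assay) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    colData = S4Vectors::DataFrame(label = as.integer(labels), row.names = ids))
  new("FeatureTable", se)
}

#' FeatureRanking: features ordered by one scoring method
#'
#' @slot method one of `"variance"`, `"chi2"`, `"mic"`, `"lr"`, `"linsvm"`,
#'   `"rf"`.
#' @slot orderedNames feature names sorted by descending score (stable on
#'   ties, original column order).
#' @slot scores named numeric score per feature.
#' @exportClass FeatureRanking
setClass("FeatureRanking",
  representation(method = "character", orderedNames = "character",
                 scores = "numeric"))

setValidity("FeatureRanking", function(object) {
  msg <- character()
  if (!setequal(object@orderedNames, names(object@scores)) ||
      length(object@orderedNames) != length(object@scores))
    msg <- c(msg, "orderedNames must be a permutation of names(scores)")
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: a surviving feature subset with provenance
#'
#' @slot origin short description, e.g. `"LR4"`, `"LinSVM20_RFE"`, `"Lasso"`.
#' @slot selectedNames the selected feature names, in ranking order.
#' @slot provenance list of the parameters that produced the subset.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(origin = "character", selectedNames = "character",
                 provenance = "list"))

#' NormalizerState: per-feature min/max learned from a training table
#' @exportClass NormalizerState
setClass("NormalizerState",
  representation(featureNames = "character", mins = "numeric", maxs = "numeric"))

setValidity("NormalizerState", function(object) {
  if (any(object@maxs < object@mins)) "max must be >= min per feature" else TRUE
})

#' MetricSet: ACC, MCC, SN, SP from confusion counts
#'
#' @slot ACC,MCC,SN,SP the four metrics (fractions; MCC in [-1, 1]).
#' @slot counts named integer vector `TP`, `TN`, `FP`, `FN`.
#' @slot degenerate names of metrics whose denominator was zero and were
#'   reported as 0 by convention.
#' @exportClass MetricSet
setClass("MetricSet",
  representation(ACC = "numeric", MCC = "numeric", SN = "numeric",
                 SP = "numeric", counts = "integer", degenerate = "character"))

#' CVReport: per-fold and pooled cross-validation metrics
#' @slot folds list of per-fold [MetricSet-class].
#' @slot pooled [MetricSet-class] over the union of held-out predictions.
#' @slot seed integer fold-assignment seed.
#' @slot classifier descriptor name of the classifier used.
#' @slot foldAssignment integer fold id per sample.
#' @exportClass CVReport
setClass("CVReport",
  representation(folds = "list", pooled = "MetricSet", seed = "integer",
                 classifier = "character", foldAssignment = "integer"))

#' ClassifierSpec: a pluggable classifier descriptor
#' @slot name one of `"gnb"`, `"knn"`, `"dt"`, `"lr"`, `"svm"`, `"linsvm"`,
#'   `"rf"`, `"gbdt"`, `"xgb"`.
#' @slot params named list of pinned parameters.
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
  representation(name = "character", params = "list"))

#' ClassifierFit: a trained classifier bound to its feature names
#' @exportClass ClassifierFit
setClass("ClassifierFit",
  representation(spec = "ClassifierSpec", model = "ANY",
                 featureNames = "character"))

#' MemberModel: one trained ensemble member
#'
#' @slot origin selection descriptor, e.g. `"emb_All/LR20_RFE"`.
#' @slot featureNames the member's selected feature subset.
#' @slot fit trained [ClassifierFit-class].
#' @slot normalizer the member's own [NormalizerState-class].
#' @slot cvAcc pooled five-fold CV accuracy, in (0, 1].
#' @exportClass MemberModel
setClass("MemberModel",
  representation(origin = "character", featureNames = "character",
                 fit = "ClassifierFit", normalizer = "NormalizerState",
                 cvAcc = "numeric"))

setValidity("MemberModel", function(object) {
  msg <- character()
  if (!(length(object@cvAcc) == 1L && object@cvAcc > 0))
    msg <- c(msg, "cvAcc must be a single positive value")
  if (length(object@featureNames) < 1L)
    msg <- c(msg, "featureNames must be nonempty")
  if (length(msg)) msg else TRUE
})

#' EnsembleModel: accuracy-weighted soft-voting ensemble
#'
#' @slot members list of [MemberModel-class].
#' @slot weights CV-accuracy-proportional weights, summing to 1.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(members = "list", weights = "numeric"))

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) != length(object@weights))
    msg <- c(msg, "one weight per member required")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' FeatureSetSpec: which descriptor categories to assemble
#'
#' @slot categories subset of `c("avg", "sep", "aa", "corr")`.
#' @slot kValues separation distances (default 2:3).
#' @slot phiValues correlation lags (default 1:3).
#' @slot aaAlphabet ordered 20-letter amino-acid alphabet.
#' @slot d representation dimension.
#' @exportClass FeatureSetSpec
setClass("FeatureSetSpec",
  representation(categories = "character", kValues = "integer",
                 phiValues = "integer", aaAlphabet = "character",
                 d = "integer"))

setValidity("FeatureSetSpec", function(object) {
  msg <- character()
  if (!all(object@categories %in% c("avg", "sep", "aa", "corr")))
    msg <- c(msg, "unknown feature category")
  if (any(object@kValues < 2L)) msg <- c(msg, "kValues must be >= 2")
  if (any(object@phiValues < 1L)) msg <- c(msg, "phiValues must be positive")
  if (length(object@aaAlphabet) != 20L || anyDuplicated(object@aaAlphabet))
    msg <- c(msg, "aaAlphabet must hold exactly 20 distinct letters")
  if (object@d < 1L) msg <- c(msg, "d must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic two-class generator
#'
#' @slot nPos,nNeg class sizes.
#' @slot lengthRange inclusive range protein lengths are drawn from.
#' @slot d representation dimension.
#' @slot informativeDims number m of class-informative dimensions.
#' @slot effectSize raw-score class-mean shift delta added to informative
#'   dimensions of positive proteins.
#' @slot noiseSd raw-score standard deviation sigma.
#' @slot seed RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nPos = "integer", nNeg = "integer", lengthRange = "integer",
                 d = "integer", informativeDims = "integer",
                 effectSize = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@informativeDims > object@d) msg <- c(msg, "informativeDims must be <= d")
  if (object@informativeDims < 0L) msg <- c(msg, "informativeDims must be >= 0")
  if (any(object@lengthRange < 2L)) msg <- c(msg, "lengths must be >= 2")
  if (object@lengthRange[2] < object@lengthRange[1])
    msg <- c(msg, "lengthRange must be increasing")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@nPos < 1L || object@nNeg < 1L) msg <- c(msg, "need at least one sample per class")
  if (length(msg)) msg else TRUE
})
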