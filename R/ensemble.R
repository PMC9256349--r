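#' @include AllClasses.R classifiers.R evaluation.R
NULL

#' Accuracy-proportional soft-voting weights
#'
#' w_i = ACC_i / sum_k ACC_k over the member CV accuracies.
#'
#' @param cvAccs positive accuracy vector.
#' @return weights summing to 1.
#' @examples
#' computeWeights(c(0.9, 0.6, 0.5))  # 0.45 0.30 0.25
#' @export
computeWeights <- function(cvAccs) {
  if (!length(cvAccs) || any(!is.finite(cvAccs)) || any(cvAccs <= 0))
    stop("all member accuracies must be positive")
  cvAccs / sum(cvAccs)
}

#' Construct one ensemble member
#'
#' @param origin unique selection descriptor, e.g. `"emb_All/LR4_RFE"`.
#' @param featureNames the member's selected feature subset (names into the
#'   raw descriptor columns the ensemble is scored on).
#' @param fit trained [ClassifierFit-class] on the normalized subset.
#' @param normalizer the member's [NormalizerState-class] (fit on training
#'   data, restricted to the subset).
#' @param cvAcc pooled five-fold CV accuracy of the member.
#' @return A [MemberModel-class].
#' @export
memberModel <- function(origin, featureNames, fit, normalizer, cvAcc) {
  new("MemberModel", origin = origin, featureNames = featureNames,
      fit = fit, normalizer = normalizer, cvAcc = cvAcc)
}

#' Build an accuracy-weighted soft-voting ensemble
#'
#' @param members list of [MemberModel-class] with unique origins.
#' @return An [EnsembleModel-class]; weights are CV-accuracy proportional.
#' @export
buildEnsemble <- function(members) {
  if (!length(members)) stop("no members")
  org <- vapply(members, function(m) m@origin, character(1))
  if (anyDuplicated(org))
    stop("duplicate member origins: ",
         paste(unique(org[duplicated(org)]), collapse = ", "))
  accs <- vapply(members, function(m) m@cvAcc, numeric(1))
  new("EnsembleModel", members = members, weights = computeWeights(accs))
}

#' @export
#' @rdname predictProba
setMethod("predictProba", "EnsembleModel", function(object, newdata) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x)))
    stop("ensemble input needs named descriptor columns")
  n <- nrow(x)
  p1 <- numeric(n)
  for (i in seq_along(object@members)) {
    m <- object@members[[i]]
    missing <- setdiff(m@featureNames, colnames(x))
    if (length(missing))
      stop("member '", m@origin, "' cannot score the input: missing ",
           paste(utils::head(missing, 3), collapse = ", "))
    sub <- x[, m@featureNames, drop = FALSE]
    normed <- minmaxApply(m@normalizer, sub)
    pr <- predictProba(m@fit, normed)
    if (anyNA(pr))
      stop("member '", m@origin, "' produced no probability output")
    p1 <- p1 + object@weights[i] * pr[, "p1"]
  }
  cbind(p0 = 1 - p1, p1 = p1)
})

#' @export
#' @rdname predictClass
setMethod("predictClass", "EnsembleModel", function(object, newdata) {
  # tie at 0.5 goes to the positive (DNA-binding) class
  as.integer(predictProba(object, newdata)[, "p1"] >= 0.5)
})

#' Ensemble manifest: origins, accuracies and weights
#'
#' @param ensemble an [EnsembleModel-class].
#' @param path optional JSON output file.
#' @param modelPaths optional per-member serialized-model file paths.
#' @return the manifest list, invisibly if written.
#' @export
ensembleManifest <- function(ensemble, path = NULL, modelPaths = NULL) {
  man <- list(
    members = lapply(seq_along(ensemble@members), function(i) {
      m <- ensemble@members[[i]]
      out <- list(origin = m@origin, cvAcc = m@cvAcc,
                  weight = ensemble@weights[i],
                  nFeatures = length(m@featureNames),
                  classifier = m@fit@spec@name)
      if (!is.null(modelPaths)) out$modelPath <- modelPaths[i]
      out
    }))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
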