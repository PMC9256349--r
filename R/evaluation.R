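#' @include AllClasses.R classifiers.R
NULL

.ftValues <- function(x) {
  if (is(x, "FeatureTable")) featureMatrix(x) else as.matrix(x)
}

#' Learn per-feature min/max from a training table
#'
#' @param table a [FeatureTable-class] or samples x features matrix.
#' @return A [NormalizerState-class].
#' @export
minmaxFit <- function(table) {
  v <- .ftValues(table)
  if (nrow(v) < 1L) stop("need at least one row")
  new("NormalizerState", featureNames = colnames(v),
      mins = apply(v, 2L, min), maxs = apply(v, 2L, max))
}

#' Apply MinMax normalization learned from a training table
#'
#' Maps x to (x - min) / (max - min) per feature. Constant training columns
#' map to 0; values outside the training range are not clipped, so test-set
#' values may fall outside the unit interval.
#'
#' @param state a [NormalizerState-class] from [minmaxFit()].
#' @param table a [FeatureTable-class] or matrix whose feature names match
#'   the state.
#' @return object of the same type as `table`, normalized.
#' @export
minmaxApply <- function(state, table) {
  v <- .ftValues(table)
  if (!identical(colnames(v), state@featureNames)) {
    if (!all(state@featureNames %in% colnames(v)))
      stop("feature names do not match the normalizer state")
    v <- v[, state@featureNames, drop = FALSE]
  }
  span <- state@maxs - state@mins
  out <- sweep(v, 2L, state@mins)
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], "/")
  out[, !nz] <- 0
  if (is(table, "FeatureTable"))
    FeatureTable(out, classLabels(table), ids = sampleIds(table))
  else out
}

#' Confusion counts from truth and prediction vectors
#' @param truth,pred binary 0/1 vectors of equal length.
#' @return named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  c(TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L))
}

#' ACC, MCC, SN and SP from confusion counts
#'
#' ACC = (TP + TN) / total, SN = TP / (TP + FN), SP = TN / (TN + FP), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)). Whenever a
#' denominator is zero the metric is reported as 0 and flagged in the
#' `degenerate` slot.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN` (as from
#'   [confusionCounts()]), or the TP count if the four are given separately.
#' @param tn,fp,fn optional separate counts.
#' @return A [MetricSet-class].
#' @examples
#' computeMetrics(c(TP = 3, TN = 2, FP = 2, FN = 1))@MCC  # 4 / sqrt(240)
#' @export
computeMetrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.null(tn)) counts <- c(TP = counts, TN = tn, FP = fp, FN = fn)
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("need nonnegative TP, TN, FP, FN")
  tp <- counts["TP"]; tn <- counts["TN"]; fp <- counts["FP"]; fn <- counts["FN"]
  total <- sum(counts)
  if (total < 1) stop("confusion counts must sum to at least 1")
  deg <- character(0)
  acc <- unname((tp + tn) / total)
  if (tp + fn > 0) sn <- unname(tp / (tp + fn)) else { sn <- 0; deg <- c(deg, "SN") }
  if (tn + fp > 0) sp <- unname(tn / (tn + fp)) else { sp <- 0; deg <- c(deg, "SP") }
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  if (denom > 0) mcc <- unname((tp * tn - fn * fp) / sqrt(denom))
  else { mcc <- 0; deg <- c(deg, "MCC") }
  new("MetricSet", ACC = acc, MCC = mcc, SN = sn, SP = sp,
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      degenerate = deg)
}

#' Metrics as a named numeric vector
#' @param m a [MetricSet-class].
#' @param percent report ACC/SN/SP as percentages (MCC stays on [-1, 1]).
#' @return named numeric vector ACC, MCC, SN, SP.
#' @export
metricVector <- function(m, percent = FALSE) {
  f <- if (percent) 100 else 1
  c(ACC = m@ACC * f, MCC = m@MCC, SN = m@SN * f, SP = m@SP * f)
}

# stratified fold assignment: per class, shuffle then deal cyclically
.stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validation of one classifier on one table
#'
#' Protocol default (`normalize = "once"`): the whole table is MinMax
#' normalized once before splitting, mirroring a train-then-CV pipeline in
#' which normalization precedes fold assignment. `"per-fold"` refits the
#' normalizer inside every fold for leakage-free evaluation; `"none"` assumes
#' the caller normalized. Pooled metrics are computed from the union of all
#' held-out predictions (counts, not fold averages).
#'
#' @param table a [FeatureTable-class].
#' @param classifier a [ClassifierSpec-class] (default Gaussian-kernel SVM).
#' @param folds number of folds (default 5).
#' @param seed fold-assignment and fitting seed.
#' @param normalize `"once"`, `"per-fold"` or `"none"`.
#' @return A [CVReport-class].
#' @export
crossValidate <- function(table, classifier = classifierSpec("svm"),
                          folds = 5L, seed = 1L,
                          normalize = c("once", "per-fold", "none")) {
  normalize <- match.arg(normalize)
  y <- classLabels(table)
  if (length(unique(y)) < 2L) stop("cross-validation needs both classes")
  if (folds > min(table(y))) stop("folds exceed the minority class count")
  raw <- featureMatrix(table)
  if (normalize == "once") raw <- minmaxApply(minmaxFit(raw), raw)
  assign <- .stratifiedFolds(y, folds, seed)
  predAll <- integer(length(y))
  foldMetrics <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- assign != f
    xtr <- raw[tr, , drop = FALSE]; xte <- raw[!tr, , drop = FALSE]
    if (normalize == "per-fold") {
      st <- minmaxFit(xtr)
      xtr <- minmaxApply(st, xtr); xte <- minmaxApply(st, xte)
    }
    fit <- fitClassifier(classifier, xtr, y[tr], seed = seed + f)
    pf <- predictClass(fit, xte)
    predAll[!tr] <- pf
    foldMetrics[[f]] <- computeMetrics(confusionCounts(y[!tr], pf))
  }
  new("CVReport", folds = foldMetrics,
      pooled = computeMetrics(confusionCounts(y, predAll)),
      seed = as.integer(seed), classifier = classifier@name,
      foldAssignment = assign)
}

#' Pooled accuracy of a CV report
#' @param report a [CVReport-class].
#' @return pooled accuracy in [0, 1].
#' @export
pooledAcc <- function(report) report@pooled@ACC

#' Fit on a training table, evaluate on an independent test table
#'
#' The normalizer is learned from the training table only and applied to the
#' test table; the model is fitted on the whole normalized training table.
#'
#' @param train,test [FeatureTable-class] objects with matching feature names.
#' @param classifier a [ClassifierSpec-class].
#' @param seed fitting seed.
#' @return list with `fit` ([ClassifierFit-class]), `normalizer`
#'   ([NormalizerState-class]) and `metrics` ([MetricSet-class]) on the test
#'   predictions.
#' @export
fitAndTest <- function(train, test, classifier = classifierSpec("svm"),
                       seed = 1L) {
  if (!identical(featureNames(train), featureNames(test)))
    stop("train and test feature names do not match")
  st <- minmaxFit(train)
  xtr <- minmaxApply(st, featureMatrix(train))
  xte <- minmaxApply(st, featureMatrix(test))
  fit <- fitClassifier(classifier, xtr, classLabels(train), seed = seed)
  pred <- predictClass(fit, xte)
  list(fit = fit, normalizer = st,
       metrics = computeMetrics(confusionCounts(classLabels(test), pred)))
}
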