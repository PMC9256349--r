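#' @include AllClasses.R evaluation.R lars.R
NULL

.rankingLabel <- c(variance = "Var", chi2 = "Chi2", mic = "MIC",
                   lr = "LR", linsvm = "LinSVM", rf = "RF")

.makeRanking <- function(method, names, scores) {
  scores <- as.numeric(scores)
  names(scores) <- names
  ord <- order(-scores)               # stable: ties keep original column order
  new("FeatureRanking", method = method, orderedNames = names[ord],
      scores = scores)
}

#' Rank features by population variance
#'
#' @param table a [FeatureTable-class] with at least two rows.
#' @return A [FeatureRanking-class], descending variance, stable ties.
#' @export
scoreVariance <- function(table) {
  x <- featureMatrix(table)
  if (nrow(x) < 2L) stop("variance ranking needs at least two samples")
  v <- colMeans(x * x) - colMeans(x)^2
  v[v < 0] <- 0                        # guard tiny negative rounding
  .makeRanking("variance", colnames(x), v)
}

#' Rank features by the chi-squared statistic against the class label
#'
#' For nonnegative (MinMax-normalized) features: per class c the observed
#' mass is O_c = sum of the feature over class-c rows, the expected mass
#' E_c = (total sum) * n_c / n, and the score is sum_c (O_c - E_c)^2 / E_c.
#' A feature with zero total mass scores 0 by convention.
#'
#' @inheritParams scoreVariance
#' @return A [FeatureRanking-class].
#' @export
scoreChi2 <- function(table) {
  x <- featureMatrix(table)
  if (min(x) < 0) stop("chi-squared ranking requires nonnegative features; ",
                       "MinMax-normalize the table first")
  y <- classLabels(table)
  n <- length(y)
  sc <- numeric(ncol(x))
  tot <- colSums(x)
  for (cl in c(0L, 1L)) {
    obs <- colSums(x[y == cl, , drop = FALSE])
    expd <- tot * sum(y == cl) / n
    ok <- expd > 0
    sc[ok] <- sc[ok] + (obs[ok] - expd[ok])^2 / expd[ok]
  }
  sc[tot == 0] <- 0
  .makeRanking("chi2", colnames(x), sc)
}

#' Maximal information coefficient of two vectors
#'
#' MIC per the characteristic-matrix definition: over all x-bins x y-bins
#' grids with bin-count product bounded by B(n) = max(n^alpha, 4), the
#' maximum of I(binned x; binned y) / log2(min(bins)). The search
#' equipartitions one axis by rank and optimizes the other exactly by
#' dynamic programming, in both orientations, so the statistic is symmetric
#' and lies in [0, 1]. Constant input gives 0 by convention.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param alpha grid-bound exponent (default 0.6).
#' @return MIC value in [0, 1].
#' @examples
#' micStatistic(1:16, (1:16)^3)  # 1: noiseless functional relationship
#' @export
micStatistic <- function(x, y, alpha = 0.6) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("MIC needs at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  .micCpp(as.numeric(x), as.numeric(y), alpha)
}

#' Rank features by MIC against the class label
#' @inheritParams scoreVariance
#' @param alpha grid-bound exponent passed to [micStatistic()].
#' @return A [FeatureRanking-class].
#' @export
scoreMIC <- function(table, alpha = 0.6) {
  x <- featureMatrix(table)
  y <- as.numeric(classLabels(table))
  sc <- apply(x, 2L, function(col)
    if (stats::var(col) == 0) 0 else .micCpp(col, y, alpha))
  .makeRanking("mic", colnames(x), sc)
}

#' Rank features by an embedded estimator fitted on the whole table
#'
#' The estimator is fitted once on the full (normalized) table; scores are
#' absolute linear coefficients for `lr` (ridge-penalized logistic
#' regression) and `linsvm` (linear-kernel SVM weight vector), and
#' normalized impurity importances (summing to 1) for `rf`.
#'
#' @inheritParams scoreVariance
#' @param estimator `"lr"`, `"linsvm"` or `"rf"`.
#' @param seed fixes stochastic fitting (random forest).
#' @return A [FeatureRanking-class].
#' @export
scoreEmbedded <- function(table, estimator = c("lr", "linsvm", "rf"),
                          seed = 1L) {
  estimator <- match.arg(estimator)
  x <- featureMatrix(table)
  y <- classLabels(table)
  if (length(unique(y)) < 2L) stop("embedded ranking needs both classes")
  set.seed(seed)
  sc <- switch(estimator,
    lr = {
      fit <- glmnet::glmnet(.padX(x), factor(y, levels = c(0L, 1L)),
                            family = "binomial", alpha = 0,
                            lambda = 1 / nrow(x), standardize = FALSE)
      abs(as.numeric(fit$beta))[seq_len(ncol(x))]
    },
    linsvm = {
      fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
                        cost = 1, scale = FALSE)
      abs(drop(crossprod(fit$coefs, fit$SV)))
    },
    rf = {
      fit <- ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                            importance = "impurity", num.trees = 500L,
                            seed = seed, num.threads = 1L)
      imp <- fit$variable.importance[colnames(x)]
      imp[is.na(imp)] <- 0
      if (sum(imp) > 0) imp / sum(imp) else imp
    })
  .makeRanking(estimator, colnames(x), sc)
}

#' Keep the top p percent of a ranking
#'
#' The subset size is `ceiling(p/100 * n)`, guaranteeing a nonempty subset
#' for any positive percentage; e.g. 20% of 580 features keeps 116 and 4% of
#' 37120 keeps 1485.
#'
#' @param ranking a [FeatureRanking-class].
#' @param p percentage in (0, 100].
#' @return A [SelectionResult-class] whose origin records method and p
#'   (e.g. `"LinSVM20"`).
#' @export
selectTopPercent <- function(ranking, p) {
  if (!is.numeric(p) || p <= 0 || p > 100) stop("p must be in (0, 100]")
  n <- length(ranking@orderedNames)
  keep <- ceiling(p / 100 * n)
  lab <- .rankingLabel[[ranking@method]] %||% ranking@method
  new("SelectionResult", origin = sprintf("%s%g", lab, p),
      selectedNames = ranking@orderedNames[seq_len(keep)],
      provenance = list(method = ranking@method, percent = p,
                        nFeatures = keep, of = n))
}

#' Select features by the support of a sparse linear model
#'
#' Fits a least-squares linear model with a sparsity-inducing penalty on the
#' 0/1 label and keeps the features with nonzero coefficients. `lasso` and
#' `elasticnet` (mixing 0.5) use coordinate descent with the penalty chosen
#' by internal 5-fold cross-validation; `lassolars` uses the in-package
#' least-angle-regression path ([larLassoPath()]) with its penalty chosen the
#' same way. The penalty used is recorded in the provenance.
#'
#' @param table a MinMax-normalized [FeatureTable-class].
#' @param method `"lasso"`, `"lassolars"` or `"elasticnet"`.
#' @param params optional overrides: `lambda` (fixed penalty), `alpha`
#'   (elastic-net mixing).
#' @param seed CV fold seed.
#' @return A [SelectionResult-class]; selected names ordered by descending
#'   absolute coefficient.
#' @export
selectByRegularizer <- function(table,
                                method = c("lasso", "lassolars", "elasticnet"),
                                params = list(), seed = 1L) {
  method <- match.arg(method)
  x <- featureMatrix(table)
  y <- as.numeric(classLabels(table))
  if (method %in% c("lasso", "elasticnet")) {
    alpha <- params$alpha %||% if (method == "lasso") 1 else 0.5
    set.seed(seed)
    if (is.null(params$lambda)) {
      cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = alpha,
                                 nfolds = 5L, standardize = FALSE)
      lambda <- cvfit$lambda.min
      fitObj <- cvfit$glmnet.fit
    } else {
      lambda <- params$lambda
      fitObj <- glmnet::glmnet(x, y, family = "gaussian", alpha = alpha,
                               standardize = FALSE)
    }
    b <- as.numeric(stats::coef(fitObj, s = lambda, exact = FALSE))[-1]
  } else {
    cv <- .larCvLambda(x, y, folds = 5L, seed = seed)
    lambda <- params$lambda %||% cv$lambda
    alpha <- 1
    b <- larCoef(cv$path, lambda)
  }
  nz <- which(abs(b) > 1e-10)
  nz <- nz[order(-abs(b[nz]))]
  origin <- c(lasso = "Lasso", lassolars = "LassoLars",
              elasticnet = "ElasticNet")[[method]]
  new("SelectionResult", origin = origin,
      selectedNames = colnames(x)[nz],
      provenance = list(method = method, alpha = alpha, lambda = lambda,
                        seed = seed, nFeatures = length(nz)))
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from a selected subset, repeatedly scores the current subset by
#' k-fold CV accuracy of the evaluation classifier, then removes the `step`
#' features with the smallest absolute coefficients of the linear ranker
#' (refitted on the current subset each round). Returns the subset whose
#' size maximized CV accuracy, taking the earliest (largest) size on ties.
#'
#' @param table a [FeatureTable-class] (normalized once internally).
#' @param start a [SelectionResult-class] with a nonempty subset.
#' @param ranker `"lr"` or `"linsvm"` coefficient ranker for elimination.
#' @param folds CV folds (default 5).
#' @param step features removed per round (default 1).
#' @param seed CV and fitting seed.
#' @param scorer [ClassifierSpec-class] scoring each subset size (default
#'   Gaussian-kernel SVM, the protocol's evaluation classifier).
#' @return A [SelectionResult-class] with origin `"<start>_RFE"`; provenance
#'   holds the (size, accuracy) trace.
#' @export
rfeCV <- function(table, start, ranker = c("lr", "linsvm"), folds = 5L,
                  step = 1L, seed = 1L, scorer = classifierSpec("svm")) {
  ranker <- match.arg(ranker)
  current <- start@selectedNames
  if (!length(current)) stop("start subset is empty")
  if (!all(current %in% featureNames(table)))
    stop("start subset contains unknown features")
  norm <- minmaxApply(minmaxFit(table), table)
  sizes <- integer(0); accs <- numeric(0); subsets <- list()
  repeat {
    sub <- norm[current, ]
    rep_ <- crossValidate(sub, scorer, folds = folds, seed = seed,
                          normalize = "none")
    sizes <- c(sizes, length(current))
    accs <- c(accs, pooledAcc(rep_))
    subsets[[length(subsets) + 1L]] <- current
    if (length(current) <= 1L) break
    rk <- scoreEmbedded(sub, ranker, seed = seed)
    ordered <- rk@orderedNames
    nDrop <- min(step, length(current) - 1L)
    current <- ordered[seq_len(length(ordered) - nDrop)]
  }
  best <- which.max(accs)              # earliest index = largest size on ties
  new("SelectionResult", origin = paste0(start@origin, "_RFE"),
      selectedNames = subsets[[best]],
      provenance = list(start = start@origin, ranker = ranker, step = step,
                        folds = folds, seed = seed, sizes = sizes,
                        accuracies = accs, chosenSize = sizes[best]))
}

#' Serialize a ranking to TSV (name, score, rank)
#' @param ranking a [FeatureRanking-class].
#' @param path output file.
#' @export
writeRankingTsv <- function(ranking, path) {
  df <- data.frame(name = ranking@orderedNames,
                   score = ranking@scores[ranking@orderedNames],
                   rank = seq_along(ranking@orderedNames))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a selection to JSON (origin, params, selected names)
#' @param sel a [SelectionResult-class].
#' @param path output file.
#' @export
writeSelectionJson <- function(sel, path) {
  jsonlite::write_json(
    list(origin = sel@origin, provenance = sel@provenance,
         selected = sel@selectedNames),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
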