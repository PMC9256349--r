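#' @include AllClasses.R
NULL

.CLASSIFIER_NAMES <- c("gnb", "knn", "dt", "lr", "svm", "linsvm", "rf",
                       "gbdt", "xgb")

# pinned default parameters of the roster ("default parameters" protocol)
.classifierDefaults <- function(name) {
  switch(name,
    gnb    = list(),
    knn    = list(k = 5L),
    dt     = list(),                        # rpart defaults
    lr     = list(lambda = NULL),           # NULL -> 1/n ridge penalty
    svm    = list(cost = 1, gamma = NULL),  # NULL -> 1/p
    linsvm = list(cost = 1),
    rf     = list(num.trees = 500L),
    gbdt   = list(nrounds = 100L, eta = 0.1, max_depth = 3L,
                  lambda = 0, alpha = 0),
    xgb    = list(nrounds = 100L, eta = 0.3, max_depth = 6L,
                  lambda = 1, alpha = 0),
    stop("unknown classifier: ", name))
}

#' Describe a classifier from the pluggable roster
#'
#' All members expose one fit / predict-probability contract. The roster:
#' Gaussian naive Bayes (`gnb`), K-nearest neighbours (`knn`), decision tree
#' (`dt`), logistic regression (`lr`, ridge-penalized so tables with more
#' features than samples fit), Gaussian-kernel SVM (`svm`), linear-kernel SVM
#' (`linsvm`), random forest (`rf`), gradient-boosted trees (`gbdt`,
#' unpenalized boosting) and XGBoost (`xgb`). Parameters are pinned defaults;
#' pass overrides through `params`.
#'
#' @param name roster name.
#' @param params named list of overrides.
#' @return A [ClassifierSpec-class].
#' @examples
#' classifierSpec("svm")
#' @export
classifierSpec <- function(name = .CLASSIFIER_NAMES, params = list()) {
  name <- match.arg(name)
  defaults <- .classifierDefaults(name)
  defaults[names(params)] <- params
  new("ClassifierSpec", name = name, params = defaults)
}

setMethod("show", "ClassifierSpec", function(object) {
  cat("ClassifierSpec '", object@name, "'", sep = "")
  if (length(object@params)) {
    shown <- vapply(object@params, function(p)
      if (is.null(p)) "auto" else paste(format(p), collapse = ","), character(1))
    cat(" (", paste(names(shown), shown, sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

# pad single-feature matrices: glmnet needs >= 2 columns
.padX <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `.pad` = 0)
}

#' Fit a roster classifier
#'
#' @param spec a [ClassifierSpec-class].
#' @param x samples x features numeric matrix (already normalized).
#' @param y binary 0/1 labels.
#' @param seed seed fixing any stochastic fitting.
#' @return A [ClassifierFit-class].
#' @export
fitClassifier <- function(spec, x, y, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("feat", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("cannot fit '", spec@name, "': a single class is present")
  set.seed(seed)
  p <- spec@params
  model <- switch(spec@name,
    gnb = {
      keep <- apply(x, 2L, stats::var) > 0
      if (!any(keep)) {
        list(prior = mean(y), degenerate = TRUE)
      } else {
        list(fit = e1071::naiveBayes(as.data.frame(x[, keep, drop = FALSE]),
                                     factor(y, levels = c(0L, 1L))),
             keep = colnames(x)[keep], degenerate = FALSE)
      }
    },
    knn = list(x = x, y = y, k = p$k, seed = seed),
    dt = {
      df <- as.data.frame(x)
      df$.label <- factor(y, levels = c(0L, 1L))
      rpart::rpart(.label ~ ., data = df, method = "class")
    },
    lr = {
      lam <- if (is.null(p$lambda)) 1 / nrow(x) else p$lambda
      glmnet::glmnet(.padX(x), factor(y, levels = c(0L, 1L)),
                     family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE)
    },
    svm = {
      g <- if (is.null(p$gamma)) 1 / ncol(x) else p$gamma
      e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                 cost = p$cost, gamma = g, scale = FALSE, probability = TRUE)
    },
    linsvm = e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
                        cost = p$cost, scale = FALSE, probability = TRUE),
    rf = ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                        probability = TRUE, num.trees = p$num.trees,
                        seed = seed, num.threads = 1L,
                        respect.unordered.factors = TRUE),
    gbdt = ,
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$eta,
                      max_depth = p$max_depth, lambda = p$lambda,
                      alpha = p$alpha, nthread = 1, seed = seed),
        data = dtrain, nrounds = p$nrounds, verbose = 0)
    })
  new("ClassifierFit", spec = spec, model = model, featureNames = colnames(x))
}

#' @export
#' @rdname predictProba
setMethod("predictProba", "ClassifierFit", function(object, newdata) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- object@featureNames
  missing <- setdiff(object@featureNames, colnames(x))
  if (length(missing))
    stop("newdata lacks features: ", paste(utils::head(missing, 3), collapse = ", "))
  x <- x[, object@featureNames, drop = FALSE]
  m <- object@model
  p1 <- switch(object@spec@name,
    gnb = {
      if (isTRUE(m$degenerate)) rep(m$prior, nrow(x))
      else {
        pr <- stats::predict(m$fit, as.data.frame(x[, m$keep, drop = FALSE]),
                             type = "raw", threshold = 0.001)
        pr[, "1"]
      }
    },
    knn = {
      set.seed(m$seed)
      pred <- class::knn(m$x, x, factor(m$y, levels = c(0L, 1L)),
                         k = min(m$k, nrow(m$x)), prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    dt = stats::predict(m, as.data.frame(x), type = "prob")[, "1"],
    lr = drop(stats::predict(m, .padX(x), type = "response")),
    svm = ,
    linsvm = {
      pr <- attr(stats::predict(m, x, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    rf = stats::predict(m, data = x, num.threads = 1L)$predictions[, "1"],
    gbdt = ,
    xgb = stats::predict(m, xgboost::xgb.DMatrix(x, nthread = 1)))
  p1 <- pmin(pmax(as.numeric(p1), 0), 1)
  cbind(p0 = 1 - p1, p1 = p1)
})

#' @export
#' @rdname predictClass
setMethod("predictClass", "ClassifierFit", function(object, newdata) {
  as.integer(predictProba(object, newdata)[, "p1"] >= 0.5)
})
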