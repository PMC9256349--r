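test_that("MinMax normalization learns training ranges and does not clip", {
  tr <- makeTable(cbind(a = c(2, 4, 6), b = c(1, 1, 1)), c(0, 1, 1))
  st <- minmaxFit(tr)
  expect_equal(unname(st@mins), c(2, 1))
  expect_equal(unname(st@maxs), c(6, 1))
  out <- featureMatrix(minmaxApply(st, tr))
  expect_equal(unname(out[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out[, "b"]), c(0, 0, 0))      # constant column -> 0
  te <- makeTable(cbind(a = 8, b = 5), 1)
  expect_equal(unname(featureMatrix(minmaxApply(st, te))[, "a"]), 1.5)  # unclipped
  expect_error(minmaxApply(st, makeTable(cbind(z = 1), 1)), "feature names")
  # single-row fit: min = max = the row
  one <- minmaxFit(makeTable(cbind(a = 3, b = -2), 0))
  expect_equal(unname(one@mins), unname(one@maxs))

  set.seed(9)
  x <- matrix(rnorm(40), 10, 4)
  tab <- makeTable(x, rep(c(0, 1), 5))
  norm <- featureMatrix(minmaxApply(minmaxFit(tab), tab))
  expect_equal(unname(apply(norm, 2, min)), rep(0, 4))
  expect_equal(unname(apply(norm, 2, max)), rep(1, 4))
})

test_that("confusion metrics match hand values and a brute-force oracle", {
  m <- computeMetrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(metricVector(m), c(ACC = 1, MCC = 1, SN = 1, SP = 1))
  m2 <- computeMetrics(c(TP = 10, TN = 0, FP = 10, FN = 0))
  expect_equal(metricVector(m2), c(ACC = 0.5, MCC = 0, SN = 1, SP = 0))
  expect_true("MCC" %in% m2@degenerate)
  m3 <- computeMetrics(c(TP = 3, TN = 2, FP = 2, FN = 1))
  expect_equal(m3@ACC, 0.625)
  expect_equal(m3@SN, 0.75)
  expect_equal(m3@SP, 0.5)
  expect_equal(m3@MCC, 4 / sqrt(240))

  set.seed(10)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    truth <- sample(0:1, n, TRUE)
    pred <- sample(0:1, n, TRUE)
    got <- metricVector(computeMetrics(confusionCounts(truth, pred)))
    expect_equal(got, bruteMetrics(truth, pred))
  }
  expect_error(computeMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "at least 1")
})

test_that("MCC symmetry: class relabelling preserves it, prediction flips negate it", {
  set.seed(13)
  for (rep in 1:20) {
    cts <- sample(0:20, 4, TRUE)
    if (sum(cts) == 0) next
    names(cts) <- c("TP", "TN", "FP", "FN")
    a <- computeMetrics(cts)@MCC
    swapped <- c(TP = cts[["TN"]], TN = cts[["TP"]], FP = cts[["FN"]], FN = cts[["FP"]])
    expect_equal(computeMetrics(swapped)@MCC, a, tolerance = 1e-12)
  }
  # flipping predictions on a balanced confusion negates MCC
  cts <- c(TP = 8, TN = 6, FP = 4, FN = 2)
  flip <- c(TP = cts[["FN"]], TN = cts[["FP"]], FP = cts[["TN"]], FN = cts[["TP"]])
  expect_equal(computeMetrics(flip)@MCC, -computeMetrics(cts)@MCC, tolerance = 1e-12)
})

test_that("stratified cross-validation separates separable data and is deterministic", {
  tab <- plantedTable(n = 40, p = 6, seed = 3)
  rep1 <- crossValidate(tab, classifierSpec("svm"), seed = 7)
  expect_equal(pooledAcc(rep1), 1)
  rep2 <- crossValidate(tab, classifierSpec("svm"), seed = 7)
  expect_equal(rep1@foldAssignment, rep2@foldAssignment)
  expect_equal(metricVector(rep1@pooled), metricVector(rep2@pooled))
  expect_length(rep1@folds, 5)

  # stratification: per-fold positive fraction close to global
  y <- classLabels(tab)
  for (f in seq_len(5)) {
    fr <- mean(y[rep1@foldAssignment == f])
    expect_lt(abs(fr - mean(y)), 1 / sum(rep1@foldAssignment == f))
  }
  expect_error(crossValidate(makeTable(matrix(runif(20), 10), rep(1, 10))),
               "both classes")
  expect_error(crossValidate(tab, folds = 25), "minority")
})

test_that("every roster classifier fits and emits calibrated probability pairs", {
  tab <- plantedTable(n = 40, p = 5, seed = 8)
  x <- featureMatrix(tab); y <- classLabels(tab)
  for (cl in c("gnb", "knn", "dt", "lr", "svm", "linsvm", "rf", "gbdt", "xgb")) {
    fit <- fitClassifier(classifierSpec(cl), x, y, seed = 2)
    pr <- predictProba(fit, x)
    expect_equal(unname(rowSums(pr)), rep(1, nrow(x)), tolerance = 1e-9)
    expect_true(all(pr >= 0 & pr <= 1))
    acc <- mean(predictClass(fit, x) == y)
    expect_gte(acc, 0.9)   # separable training data
  }
  expect_error(fitClassifier(classifierSpec("svm"), x, rep(1, nrow(x))),
               "single class")
})

test_that("train/test evaluation fits the normalizer on training data only", {
  tab <- plantedTable(n = 30, p = 5, seed = 9)
  res <- fitAndTest(tab, tab, classifierSpec("linsvm"), seed = 1)
  expect_equal(res$metrics@ACC, 1)
  expect_s4_class(res$normalizer, "NormalizerState")
  # all-positive test set: SP degenerate, flagged and reported as 0
  xa <- featureMatrix(tab)[classLabels(tab) == 1, ]
  testPos <- makeTable(xa, rep(1, nrow(xa)))
  res2 <- fitAndTest(tab, testPos, classifierSpec("linsvm"), seed = 1)
  expect_true("SP" %in% res2$metrics@degenerate)
  expect_equal(res2$metrics@SP, 0)
  expect_error(fitAndTest(tab, makeTable(cbind(z = 1), 1)), "feature names")
})

test_that("null features give chance-level pooled CV accuracy", {
  # labels independent of features: mean pooled ACC near 0.5
  set.seed(30)
  accs <- vapply(1:12, function(s) {
    x <- matrix(runif(200 * 6), 200, 6)
    tab <- makeTable(x, rep(c(0, 1), 100))
    pooledAcc(crossValidate(tab, classifierSpec("lr"), seed = s))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})
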