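test_that("variance ranking orders by population variance with stable ties", {
  x <- cbind(const = rep(0.5, 4), wide = c(0, 1, 0, 1), narrow = c(0.4, 0.6, 0.4, 0.6),
             dupA = c(0, 0, 1, 1), dupB = c(1, 1, 0, 0))
  tab <- makeTable(x, c(0, 0, 1, 1))
  rk <- scoreVariance(tab)
  expect_equal(rk@scores[["wide"]], 0.25)
  expect_equal(rk@scores[["narrow"]], 0.01)
  expect_equal(utils::tail(rk@orderedNames, 1), "const")
  expect_true(which(rk@orderedNames == "wide") < which(rk@orderedNames == "narrow"))
  # identical scores keep original column order
  expect_true(which(rk@orderedNames == "dupA") < which(rk@orderedNames == "dupB"))
  expect_error(scoreVariance(makeTable(x[1, , drop = FALSE], 1)), "two samples")
})

test_that("chi-squared scores follow the observed/expected mass formula", {
  # feature identical across a balanced table scores 0
  tab <- makeTable(cbind(same = rep(2, 4), lab = c(0, 0, 1, 1)), c(0, 0, 1, 1))
  rk <- scoreChi2(tab)
  expect_equal(rk@scores[["same"]], 0)
  # label-equal feature on balanced n=4: O=(0,2), E=(1,1) -> 2
  expect_equal(rk@scores[["lab"]], 2)
  # score is linear in a constant feature scaling
  tab3 <- makeTable(cbind(lab = c(0, 0, 1, 1), lab3 = 3 * c(0, 0, 1, 1)), c(0, 0, 1, 1))
  rk3 <- scoreChi2(tab3)
  expect_equal(rk3@scores[["lab3"]], 3 * rk3@scores[["lab"]])
  expect_error(scoreChi2(makeTable(cbind(a = c(-1, 1, 0, 0)), c(0, 0, 1, 1))),
               "nonnegative")
  # row permutation leaves chi2 and variance scores unchanged
  set.seed(8)
  x <- matrix(runif(60), 12, 5); y <- rep(c(0, 1), 6)
  perm <- sample(12)
  expect_equal(scoreChi2(makeTable(x, y))@scores,
               scoreChi2(makeTable(x[perm, ], y[perm]))@scores)
  expect_equal(scoreVariance(makeTable(x, y))@scores,
               scoreVariance(makeTable(x[perm, ], y[perm]))@scores)
})

test_that("MIC attains 1 on noiseless relations, 0 on constants, and stays in range", {
  expect_equal(micStatistic(1:16, 1:16), 1)
  expect_equal(micStatistic(1:16, (1:16)^3), 1)
  expect_equal(micStatistic(1:16, rep(2, 16)), 0)
  expect_error(micStatistic(1:3, 1:3), "at least 4")
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    v <- micStatistic(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, micStatistic(y, x), tolerance = 1e-12)
    # invariance to strictly monotone transforms
    expect_equal(v, micStatistic(exp(x), y), tolerance = 1e-12)
  }
  # independence at n=200 stays well below a real association
  set.seed(22)
  expect_lt(micStatistic(rnorm(200), rnorm(200)), 0.3)
})

test_that("the MIC dynamic program equals exhaustive grid enumeration at tiny n", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    x <- if (rep %% 3 == 0) sample(0:2, n, TRUE) else rnorm(n)
    y <- if (rep %% 4 == 0) sample(0:1, n, TRUE) else rnorm(n)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(micStatistic(x, y), bruteMic(x, y), tolerance = 1e-12)
  }
  # the DP itself, beyond the admissible-grid bound: optimize x against a
  # fixed binary partition of y, comparing with all-bin-boundary enumeration
  for (rep in 1:10) {
    n <- 12
    x <- rnorm(n); y <- rnorm(n)
    ybins <- dbpFSE:::.micEquipartition(y, 2)
    dp <- dbpFSE:::.micOptimizeAxis(x, ybins, 4)
    for (l in 2:4) {
      cuts <- utils::combn(n - 1, l - 1, simplify = FALSE)
      ord <- order(x)
      bestI <- max(vapply(cuts, function(ct) {
        edges <- c(0, ct, n)
        bin <- integer(n)
        bin[ord] <- rep(seq_along(edges[-1]), diff(edges))
        bruteMi(bin, ybins + 1L)
      }, numeric(1)))
      expect_equal(dp[l - 1], bestI, tolerance = 1e-12)
    }
  }
})

test_that("embedded rankings find planted structure and push constants last", {
  tab <- plantedTable(n = 60, p = 12, seed = 4)
  x <- featureMatrix(tab)
  x <- cbind(x, const = 0.5)
  tab <- makeTable(x, classLabels(tab))
  for (est in c("lr", "linsvm", "rf")) {
    rk <- scoreEmbedded(tab, est, seed = 1)
    expect_equal(rk@orderedNames[1], "f1")
    expect_lte(rk@scores[["const"]], min(rk@scores) + 1e-12)
  }
  rf <- scoreEmbedded(tab, "rf", seed = 1)
  expect_equal(sum(rf@scores), 1, tolerance = 1e-12)
  # single-class tables are rejected
  expect_error(scoreEmbedded(makeTable(x[1:5, ], rep(1, 5)), "lr"), "both classes")
  # determinism under a fixed seed
  expect_identical(scoreEmbedded(tab, "rf", seed = 9)@orderedNames,
                   scoreEmbedded(tab, "rf", seed = 9)@orderedNames)
})

test_that("top-percent cuts use the ceiling rule and nest monotonically", {
  fake <- function(n) new("FeatureRanking", method = "variance",
                          orderedNames = paste0("f", seq_len(n)),
                          scores = stats::setNames(rev(seq_len(n)), paste0("f", seq_len(n))))
  expect_length(selectTopPercent(fake(580), 20)@selectedNames, 116)
  expect_length(selectTopPercent(fake(37120), 4)@selectedNames, 1485)
  expect_length(selectTopPercent(fake(1280), 20)@selectedNames, 256)
  expect_equal(selectTopPercent(fake(580), 20)@origin, "Var20")
  expect_error(selectTopPercent(fake(10), 0), "in \\(0, 100")
  expect_error(selectTopPercent(fake(10), 101), "in \\(0, 100")
  rk <- fake(137)
  sizes <- integer()
  prev <- character(0)
  for (p in seq(10, 100, 10)) {
    cur <- selectTopPercent(rk, p)@selectedNames
    expect_true(all(prev %in% cur))
    prev <- cur
    sizes <- c(sizes, length(cur))
  }
  expect_equal(sizes, ceiling(seq(10, 100, 10) / 100 * 137))
})

test_that("sparse regularizers recover planted support and skip constants", {
  set.seed(14)
  ds <- generateDataset(syntheticSpec(nPos = 50, nNeg = 50, d = 12,
                                      informativeDims = 2, seed = 14))
  tab <- datasetToTable(ds, featureSetSpec(12, categories = "avg"))
  x <- cbind(featureMatrix(tab), const = 0.5)
  tab <- makeTable(x, classLabels(tab))
  avgPlanted <- paste0("avg_", ds$informative - 1L)
  for (meth in c("lasso", "lassolars", "elasticnet")) {
    sel <- selectByRegularizer(tab, meth, seed = 2)
    expect_false("const" %in% sel@selectedNames)
    expect_lte(length(sel@selectedNames), ncol(x))
    expect_true(all(avgPlanted %in% sel@selectedNames))
    expect_true(is.numeric(sel@provenance$lambda))
  }
})

test_that("the in-package LAR lasso path agrees with coordinate descent at its knots", {
  set.seed(15)
  n <- 50; p <- 12
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.numeric(x[, 2] - x[, 9] + rnorm(n, 0, 0.2) > 0)
  path <- larLassoPath(x, y)
  expect_true(all(diff(path$lambda) <= 1e-12))
  for (k in c(2, 4, length(path$lambda) - 1)) {
    lam <- path$lambda[k]
    ref <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = lam / n, standardize = FALSE, thresh = 1e-13)
    expect_equal(unname(larCoef(path, lam)), as.numeric(coef(ref))[-1],
                 tolerance = 1e-5)
  }
  # interpolated (off-knot) penalties also satisfy the lasso solution
  lamMid <- mean(path$lambda[3:4])
  ref <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lamMid / n, standardize = FALSE, thresh = 1e-13)
  expect_equal(unname(larCoef(path, lamMid)), as.numeric(coef(ref))[-1],
               tolerance = 1e-5)
})

test_that("RFECV returns a nested subset that keeps the separating feature", {
  for (seed in 1:3) {
    tab <- plantedTable(n = 40, p = 21, seed = seed)
    ntab <- minmaxApply(minmaxFit(tab), tab)
    rk <- scoreEmbedded(ntab, "linsvm", seed = seed)
    start <- selectTopPercent(rk, 50)
    res <- rfeCV(ntab, start, "linsvm", step = 2, seed = seed)
    expect_true(all(res@selectedNames %in% start@selectedNames))
    expect_gte(length(res@selectedNames), 1)
    expect_true("f1" %in% res@selectedNames)
    expect_equal(res@origin, paste0(start@origin, "_RFE"))
  }
  # a single-feature start is returned unchanged
  tab <- plantedTable(seed = 5)
  one <- new("SelectionResult", origin = "One", selectedNames = "f1",
             provenance = list())
  expect_equal(rfeCV(tab, one, "lr", seed = 1)@selectedNames, "f1")
  empty <- new("SelectionResult", origin = "none", selectedNames = character(0),
               provenance = list())
  expect_error(rfeCV(tab, empty, "lr"), "empty")
})

test_that("rankings and selections serialize to TSV and JSON", {
  tab <- plantedTable(seed = 6)
  rk <- scoreVariance(tab)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRankingTsv(rk, f)
  back <- read.delim(f)
  expect_equal(back$name, rk@orderedNames)
  expect_equal(diff(back$rank), rep(1, nrow(back) - 1))
  sel <- selectTopPercent(rk, 30)
  fj <- withr::local_tempfile(fileext = ".json")
  writeSelectionJson(sel, fj)
  got <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(got$origin, sel@origin)
  expect_equal(got$selected, sel@selectedNames)
})
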