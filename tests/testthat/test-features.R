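test_that("the four averaging operators match hand-computed values", {
  # all-residue average
  expect_equal(avgAll(rbind(c(1, 3), c(3, 5))), c(2, 4))
  expect_equal(avgAll(matrix(0.5, 4, 3)), rep(0.5, 3))
  expect_equal(avgAll(matrix(c(1, 2, 3), 1, 3)), c(1, 2, 3))

  # k-separation subsets and divisor floor((L - s + k)/k)
  m10 <- matrix(seq_len(10), 10, 1)
  expect_equal(avgSeparation(m10, 2, 1), mean(c(1, 3, 5, 7, 9)))
  expect_equal(avgSeparation(m10, 3, 3), mean(c(3, 6, 9)))
  m7 <- matrix(seq_len(7), 7, 1)
  expect_equal(avgSeparation(m7, 2, 2), mean(c(2, 4, 6)))
  expect_error(avgSeparation(m7, 9, 8), "exceeds")
  expect_error(avgSeparation(m7, 2, 3), "s <= k")

  # per-amino-acid-type averages
  m3 <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(avgByAA(m3, "AAC", "C"), c(5, 6))
  expect_equal(avgByAA(m3, "AAC", "D"), c(0, 0))
  expect_equal(avgByAA(m3, "AGA", "A"), c(3, 4))
  expect_error(avgByAA(m3, "AAC", "B"), "standard amino")

  # lagged squared-difference correlation
  expect_equal(avgCorrelation(matrix(1, 5, 2), 1), c(0, 0))
  expect_equal(avgCorrelation(matrix(c(0, 1, 3), 3, 1), 1), 2.5)
  expect_equal(avgCorrelation(matrix(c(0, 1, 3), 3, 1), 2), 9)
  expect_error(avgCorrelation(m3, 0), "phi")
  expect_warning(z <- avgCorrelation(m3, 5), "returning zeros")
  expect_equal(z, c(0, 0))
})

test_that("full assembly yields 29d features in fixed block order with unique names", {
  set.seed(3)
  L <- 40
  m <- sigmoidNormalize(ResidueMatrix(matrix(rnorm(L * 20), L, 20), "p", "pssm"))
  sq <- randomSeq(L)
  fv <- assembleFeatures(m, sq)
  expect_length(fv, 580)
  nm <- names(fv)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(sum(startsWith(nm, "avg_")), 20)
  expect_equal(sum(startsWith(nm, "sep_")), 100)
  expect_equal(sum(startsWith(nm, "aa_")), 400)
  expect_equal(sum(startsWith(nm, "corr_")), 60)
  # fixed order: avg, sep (2,1),(2,2),(3,1),(3,2),(3,3), aa alphabet, corr 1:3
  expect_equal(nm[1], "avg_0")
  expect_equal(nm[21], "sep_k2_s1_0")
  expect_equal(nm[61], "sep_k3_s1_0")
  expect_equal(nm[121], "aa_A_0")
  expect_equal(nm[141], "aa_R_0")
  expect_equal(nm[521], "corr_phi1_0")
  # avg-only set
  fvA <- assembleFeatures(m, sq, featureSetSpec(20, categories = "avg"))
  expect_length(fvA, 20)
  expect_equal(unname(fvA), unname(fv[1:20]))
  # raw matrices are rejected
  raw <- ResidueMatrix(matrix(rnorm(L * 20), L, 20), "p", "pssm")
  expect_error(assembleFeatures(raw, sq), "normalize")
})

test_that("separation and amino-acid partitions conserve the global average", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(3:60, 1)
    d <- sample(1:6, 1)
    m <- matrix(rnorm(L * d), L, d)
    sq <- randomSeq(L)
    for (k in 2:3) {
      Ns <- vapply(seq_len(k), function(s) floor((L - s + k) / k), numeric(1))
      expect_equal(sum(Ns), L)
      agg <- Reduce(`+`, lapply(seq_len(k), function(s)
        Ns[s] * avgSeparation(m, k, s))) / L
      expect_equal(agg, avgAll(m), tolerance = 1e-10)
    }
    cnt <- table(factor(strsplit(sq, "")[[1]], levels = pssmAlphabet()))
    expect_equal(sum(cnt), L)
    agg <- Reduce(`+`, lapply(pssmAlphabet(), function(t)
      cnt[[t]] * avgByAA(m, sq, t))) / L
    expect_equal(agg, avgAll(m), tolerance = 1e-10)
  }
})

test_that("correlation features are translation-invariant and nonnegative", {
  set.seed(12)
  m <- matrix(rnorm(80), 20, 4)
  for (phi in 1:3) {
    expect_true(all(avgCorrelation(m, phi) >= 0))
    expect_equal(avgCorrelation(m + 7.3, phi), avgCorrelation(m, phi),
                 tolerance = 1e-10)
  }
  # after sigmoid normalization, averaging blocks stay inside (0, 1)
  nm <- sigmoidNormalize(ResidueMatrix(m, "p", "embedding"))
  sq <- randomSeq(20)
  fv <- assembleFeatures(nm, sq)
  nonzero <- fv[startsWith(names(fv), "avg_") | startsWith(names(fv), "sep_")]
  expect_true(all(nonzero > 0 & nonzero < 1))
})

test_that("table assembly keeps row order, and rejects inconsistent inputs", {
  set.seed(5)
  ds <- generateDataset(syntheticSpec(nPos = 3, nNeg = 3, lengthRange = c(10, 15),
                                      d = 4, informativeDims = 1, seed = 2))
  mats <- lapply(ds$matrices, sigmoidNormalize)
  tab <- buildFeatureTable(mats, ds$records, ds$labels)
  expect_s4_class(tab, "FeatureTable")
  expect_equal(dim(featureMatrix(tab)), c(6L, 29L * 4L))
  expect_equal(classLabels(tab), ds$labels)
  expect_equal(sampleIds(tab), names(ds$records))

  # permutation of inputs permutes rows identically
  perm <- c(4, 2, 6, 1, 3, 5)
  tab2 <- buildFeatureTable(mats[perm], ds$records[perm], ds$labels[perm])
  expect_equal(featureMatrix(tab2), featureMatrix(tab)[perm, ])

  expect_error(buildFeatureTable(list(), ds$records[0], integer(0)), "empty")
  expect_error(buildFeatureTable(mats, ds$records, ds$labels[-1]), "label")
  mixed <- c(mats[1], list(sigmoidNormalize(
    ResidueMatrix(matrix(rnorm(20), 10, 2), "q", "embedding"))))
  expect_error(buildFeatureTable(mixed, c(ds$records[1], Biostrings::AAStringSet(q = randomSeq(10))),
                                 c(1, 0)), "mixed")
})
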