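# Shared fixtures and independent oracles, built in code at test time.

# small labelled feature table with controllable columns
makeTable <- function(values, labels) {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  FeatureTable(as.matrix(values), labels)
}

# balanced two-class table with one planted separating column among noise
plantedTable <- function(n = 40, p = 10, shift = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c(0L, 1L), each = n / 2)
  x[, 1] <- runif(n, 0, 0.3) + ifelse(y == 1, 0.7, 0)
  FeatureTable(x, y)
}

# brute-force metric oracle straight from prediction/label vectors
bruteMetrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  acc <- (tp + tn) / length(truth)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fn * fp) / sqrt(den) else 0
  c(ACC = acc, MCC = mcc, SN = sn, SP = sp)
}

# exhaustive-enumeration MIC oracle for tiny n: enumerates every contiguous
# clump partition of the optimized axis (all bin boundaries), with the fixed
# axis rank-equipartitioned, over all admissible grids in both orientations.
bruteMic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(n^alpha, 4)
  best <- 0
  for (orient in 1:2) {
    a <- if (orient == 1) x else y
    b <- if (orient == 1) y else x
    for (q in 2:max(2, floor(B / 2))) {
      lmax <- floor(B / q)
      if (lmax < 2) next
      bb <- dbpFSE:::.micEquipartition(b, q) + 1L
      ord <- order(a)
      av <- a[ord]; bv <- bb[ord]
      clumpEnd <- which(diff(av) != 0)
      m <- length(clumpEnd) + 1L
      bounds <- c(clumpEnd, n)      # cumulative point count at each clump end
      for (l in 2:lmax) {
        if (m < 2) next
        cuts <- utils::combn(seq_len(m - 1), min(l, m) - 1, simplify = FALSE)
        for (ct in cuts) {
          edges <- c(0, bounds[ct], n)
          bin <- rep(seq_along(edges[-1]), diff(edges))
          best <- max(best, bruteMi(bin, bv) / log2(min(l, q)))
        }
      }
    }
  }
  min(best, 1)
}

bruteMi <- function(px, py) {
  tab <- table(px, py)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / n *
        log2(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}

# random protein over the standard alphabet
randomSeq <- function(L) paste(sample(pssmAlphabet(), L, TRUE), collapse = "")
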