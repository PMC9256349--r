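#' @include AllClasses.R
NULL

#' Least-angle-regression lasso path
#'
#' Computes the piecewise-linear lasso coefficient path of the least-squares
#' problem by the least-angle-regression homotopy (with the lasso
#' modification: a coefficient crossing zero is dropped from the active set).
#' Columns are centered, the response is centered, neither is scaled. At
#' every knot the coefficients satisfy the lasso stationarity conditions with
#' penalty `lambda = max |X'(y - X b)|`, and the path is exactly linear in
#' lambda between knots, so [larCoef()] can interpolate to any penalty.
#'
#' @param x samples x features numeric matrix.
#' @param y numeric response (the 0/1 class label for selection use).
#' @param maxSteps cap on path steps (default `min(n - 1, p) + 30` to allow
#'   drops).
#' @param tol numerical tolerance for ties and zero crossings.
#' @return list with `lambda` (knot penalties, decreasing), `beta`
#'   (knots x features coefficient matrix), `meanx`, `meany`.
#' @export
larLassoPath <- function(x, y, maxSteps = NULL, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("feat", seq_len(p))
  if (is.null(maxSteps)) maxSteps <- min(n - 1L, p) + 30L
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  yc <- y - ym
  ignore <- colSums(xc^2) < tol          # constant columns can never enter
  beta <- numeric(p)
  mu <- numeric(n)
  active <- integer(0)
  lambdas <- numeric(0)
  betas <- list()
  for (step in seq_len(maxSteps)) {
    cvec <- drop(crossprod(xc, yc - mu))
    cvec[ignore] <- 0
    C <- max(abs(cvec))
    lambdas <- c(lambdas, C)
    betas[[length(betas) + 1L]] <- beta
    if (C < tol) break
    inactive <- setdiff(which(!ignore), active)
    newJ <- inactive[abs(cvec[inactive]) >= C - tol * max(1, C)]
    active <- c(active, newJ)
    k <- length(active)
    s <- sign(cvec[active])
    XA <- xc[, active, drop = FALSE] * rep(s, each = n)
    G <- crossprod(XA)
    Ginv1 <- tryCatch(solve(G, rep(1, k)),
                      error = function(e) solve(G + diag(1e-10, k), rep(1, k)))
    AA <- 1 / sqrt(sum(Ginv1))
    wA <- AA * Ginv1
    u <- drop(XA %*% wA)
    avec <- drop(crossprod(xc, u))
    avec[ignore] <- 0
    gammaFull <- C / AA
    others <- setdiff(which(!ignore), active)
    gamma <- gammaFull
    if (length(others)) {
      g1 <- (C - cvec[others]) / (AA - avec[others])
      g2 <- (C + cvec[others]) / (AA + avec[others])
      cand <- c(g1, g2)
      cand <- cand[is.finite(cand) & cand > tol]
      if (length(cand)) gamma <- min(c(cand, gammaFull))
    }
    d <- s * wA
    gammaj <- -beta[active] / d
    crossing <- which(is.finite(gammaj) & gammaj > tol & gammaj < gamma - tol)
    dropJ <- integer(0)
    if (length(crossing)) {
      gamma <- min(gammaj[crossing])
      dropJ <- active[which(abs(gammaj - gamma) <= tol * max(1, gamma))]
    }
    beta[active] <- beta[active] + gamma * d
    mu <- mu + gamma * u
    if (length(dropJ)) {
      beta[dropJ] <- 0
      active <- setdiff(active, dropJ)
    }
    if (length(active) >= min(n - 1L, sum(!ignore))) {
      cvec <- drop(crossprod(xc, yc - mu))
      cvec[ignore] <- 0
      lambdas <- c(lambdas, max(abs(cvec)))
      betas[[length(betas) + 1L]] <- beta
      break
    }
  }
  B <- do.call(rbind, betas)
  colnames(B) <- colnames(x)
  list(lambda = lambdas, beta = B, meanx = xm, meany = ym)
}

#' Coefficients of a LAR lasso path at an arbitrary penalty
#'
#' @param path result of [larLassoPath()].
#' @param lambda penalty value; clamped to the path range (larger than the
#'   first knot gives the zero vector, smaller than the last gives the final
#'   knot).
#' @return named coefficient vector.
#' @export
larCoef <- function(path, lambda) {
  lam <- path$lambda
  if (lambda >= lam[1]) return(path$beta[1, ])
  m <- length(lam)
  if (lambda <= lam[m]) return(path$beta[m, ])
  k <- max(which(lam >= lambda))        # lam[k] >= lambda > lam[k+1]
  if (k == m) return(path$beta[m, ])
  span <- lam[k] - lam[k + 1]
  frac <- if (span <= 0) 1 else (lam[k] - lambda) / span
  path$beta[k, ] + frac * (path$beta[k + 1, ] - path$beta[k, ])
}

#' Predict from a LAR lasso path at a penalty
#' @inheritParams larCoef
#' @param newx samples x features matrix on the original scale.
#' @return numeric predictions.
#' @export
larPredict <- function(path, lambda, newx) {
  b <- larCoef(path, lambda)
  drop(sweep(as.matrix(newx), 2L, path$meanx) %*% b) + path$meany
}

# 5-fold CV choice of the LAR lasso penalty over the full-path knot grid
.larCvLambda <- function(x, y, folds = 5L, seed = 1L) {
  full <- larLassoPath(x, y)
  grid <- unique(full$lambda)
  if (length(grid) < 2L) return(list(path = full, lambda = grid[1]))
  set.seed(seed)
  n <- nrow(x)
  fold <- sample(rep_len(seq_len(folds), n))
  err <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    pf <- larLassoPath(x[tr, , drop = FALSE], y[tr])
    for (g in seq_along(grid)) {
      pred <- larPredict(pf, grid[g], x[!tr, , drop = FALSE])
      err[f, g] <- mean((y[!tr] - pred)^2)
    }
  }
  mse <- colMeans(err)
  list(path = full, lambda = grid[which.min(mse)], cvMse = mse, grid = grid)
}
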