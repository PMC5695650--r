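#' @include utils.R
NULL

# Distribution of the doubled signed-rank statistic over all 2^n sign
# assignments, by generating-function convolution on the integer grid of
# doubled midranks. Returns counts over 0..sum(dr).
signedRankCounts <- function(dr) {
  total <- sum(dr)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in dr) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total - r + 1L)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test (exact with ties)
#'
#' Two-sided one-sample signed-rank test against a zero median. Zero
#' differences are dropped before ranking and ties receive midranks. With
#' fewer than 5 non-zero differences the test is uninformative and p = 1 by
#' convention. For up to \code{exactMax} non-zero differences the p-value is
#' exact (full enumeration of the sign-assignment distribution via a
#' generating-function convolution, valid under ties); above that a normal
#' approximation with midrank variance and continuity correction is used.
#' The two-sided p-value is the probability, under random sign assignment,
#' of a statistic at least as far from its mean as observed (the
#' distribution is symmetric about its mean even with midranks).
#'
#' @param x numeric vector of paired differences (NA dropped)
#' @param exactMax largest n for which the exact distribution is enumerated
#'   (default 25)
#' @return two-sided p-value in (0, 1]
#' @export
wilcoxonSignedRank <- function(x, exactMax = 25L) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input", call. = FALSE)
  x <- x[x != 0]
  n <- length(x)
  if (n < 5L) return(1)
  r <- rank(abs(x))
  dr <- as.integer(round(2 * r))
  w <- sum(dr[x > 0])                  # doubled W+
  mu <- sum(dr) / 2
  dev <- abs(w - mu)
  if (n <= exactMax) {
    f <- signedRankCounts(dr)
    s <- 0:(length(f) - 1L)
    p <- sum(f[abs(s - mu) >= dev - 1e-9]) / 2^n
  } else {
    sigma <- sqrt(sum(dr^2)) / 2
    z <- max(dev - 1, 0) / sigma       # continuity: 1 = doubled half-step
    p <- 2 * stats::pnorm(-z)
  }
  min(p, 1)
}

# Counts of k-subsets of the doubled midranks with each achievable sum,
# by subset-sum DP. Returns a (k+1) x (S+1) matrix of counts.
rankSumCounts <- function(dr, k) {
  S <- sum(dr)
  f <- matrix(0, nrow = k + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (r in dr) {
    for (j in k:1L) {
      idx <- (r + 1L):(S + 1L)
      f[j + 1L, idx] <- f[j + 1L, idx] + f[j, idx - r]
    }
  }
  f
}

#' Wilcoxon rank-sum test (exact with ties)
#'
#' Two-sided two-sample rank-sum test. Ties across the pooled sample
#' receive midranks. For pooled sizes up to \code{exactMax} the null
#' distribution of the first sample's rank sum is enumerated exactly over
#' all subsets (valid under ties); above that a normal approximation with
#' tie-corrected variance and continuity correction is used. Two-sided
#' p-values double the smaller tail (capped at 1).
#'
#' @param x,y numeric samples (NA dropped)
#' @param exactMax largest pooled size for exact enumeration (default 30)
#' @return two-sided p-value in (0, 1]
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 30L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("empty input", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  dr <- as.integer(round(2 * r))
  u <- sum(dr[seq_len(nx)])
  N <- nx + ny
  if (N <= exactMax) {
    f <- rankSumCounts(dr, nx)
    counts <- f[nx + 1L, ]
    tot <- sum(counts)
    s <- 0:(length(counts) - 1L)
    pl <- sum(counts[s <= u + 1e-9]) / tot
    pu <- sum(counts[s >= u - 1e-9]) / tot
    p <- 2 * min(pl, pu)
  } else {
    mu <- nx * (N + 1)                     # doubled-scale mean
    ties <- table(dr)
    sig2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- 2 * sqrt(sig2)                # doubled scale
    z <- max(abs(u - mu) - 1, 0) / sigma
    p <- 2 * stats::pnorm(-z)
  }
  min(p, 1)
}

#' Benjamini-Hochberg false-discovery-rate rejection flags
#'
#' Step-up FDR control at level \code{alpha} over one family of p-values.
#' NA p-values are never rejected and do not count toward the family size.
#'
#' @param pvals numeric vector of p-values in [0, 1]
#' @param alpha FDR level (default 0.05)
#' @return logical vector of rejections, same length as \code{pvals}
#' @export
fdrBH <- function(pvals, alpha = 0.05) {
  stopIfNot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
            "p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  out <- !is.na(adj) & adj <= alpha
  out
}

#' Quantile (median) regression by iteratively reweighted least squares
#'
#' Minimizes the check loss sum(rho_tau(y - X b)) by IRLS with
#' epsilon-smoothed weights. On data admitting an exact fit the solution
#' interpolates exactly (the least-squares start already has zero
#' residuals). Intercept-only designs short-circuit to the sample
#' quantile, the closed-form minimizer.
#'
#' @param X design matrix
#' @param y response
#' @param tau quantile in (0, 1) (default 0.5)
#' @param maxit,tol IRLS iteration controls
#' @param start optional warm-start coefficients (e.g. the full-sample fit,
#'   for bootstrap refits)
#' @return named coefficient vector
#' @export
fitQuantile <- function(X, y, tau = 0.5, maxit = 50L, tol = 1e-9,
                        start = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 1L && all(X == 1)) {
    n <- length(y)
    ys <- sort(y)
    k <- tau * n
    b <- if (abs(k - round(k)) < 1e-12) (ys[round(k)] + ys[round(k) + 1L]) / 2
         else ys[ceiling(k)]
    return(stats::setNames(b, colnames(X)[1L] %||% "(Intercept)"))
  }
  eps <- 1e-6 * (stats::sd(y) + 1e-12)
  b <- if (is.null(start)) .lm.fit(X, y)$coefficients else start
  halfTau <- tau == 0.5
  for (it in seq_len(maxit)) {
    r <- as.vector(y - X %*% b)
    a <- abs(r)
    a[a < eps] <- eps
    wq <- if (halfTau) 0.5 / a else (tau + (1 - 2 * tau) * (r <= 0)) / a
    sw <- sqrt(wq)
    bNew <- .lm.fit(X * sw, y * sw)$coefficients
    if (max(abs(bNew - b)) < tol * (1 + max(abs(b)))) { b <- bNew; break }
    b <- bNew
  }
  # vertex polish: a check-loss optimum interpolates p observations, so
  # descend over exact fits through the p smallest-residual points
  loss <- function(bb) {
    r <- y - X %*% bb
    sum(r * (tau - (r < 0)))
  }
  cur <- loss(b)
  for (it in 1:10) {
    r <- abs(as.vector(y - X %*% b))
    ix <- order(r)[seq_len(p)]
    Xi <- X[ix, , drop = FALSE]
    bv <- tryCatch(solve(Xi, y[ix]), error = function(e) NULL)
    if (is.null(bv)) break
    lv <- loss(bv)
    if (lv < cur - 1e-12 * (1 + cur)) { b <- bv; cur <- lv } else break
  }
  stats::setNames(drop(b), colnames(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
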