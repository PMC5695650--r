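# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive (full enumeration, triple
# loops, Floyd-Warshall) and shares no code with the implementation paths it
# checks.

# --- exact test oracles -----------------------------------------------------

# two-sided signed-rank p by enumerating all 2^n sign assignments
bruteSignedRank <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- as.vector(signs %*% r)
  mean(abs(wAll - mu) >= abs(w - mu) - 1e-9)
}

# two-sided rank-sum p by enumerating all n-subsets of the pooled ranks
bruteRankSum <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(r), nx)
  uAll <- apply(combs, 2L, function(ix) sum(r[ix]))
  pl <- mean(uAll <= u + 1e-9)
  pu <- mean(uAll >= u - 1e-9)
  min(1, 2 * min(pl, pu))
}

# --- network metric oracles -------------------------------------------------

# all four weighted metrics by direct formula evaluation on an adjacency
# matrix (0 = no edge); shortest paths by Floyd-Warshall
bruteNetworkMetrics <- function(W) {
  N <- nrow(W)
  edges <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  K <- nrow(edges)
  D <- 2 * K / (N * (N - 1))
  if (K == 0) return(list(rw = NA_real_, Tw = 0, D = 0, Ew = 0))
  Ws <- W / max(W)
  num <- 0
  for (i in 1:N) for (j in 1:N) for (h in 1:N)
    if (i != j && i != h && j != h)
      num <- num + (Ws[i, j] * Ws[i, h] * Ws[j, h])^(1 / 3)
  k <- rowSums(W > 0)
  den <- sum(k * (k - 1))
  Tw <- if (den > 0) num / den else 0
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  for (via in 1:N) for (i in 1:N) for (j in 1:N)
    if (L[i, via] + L[via, j] < L[i, j])
      L[i, j] <- L[i, via] + L[via, j]
  inv <- ifelse(is.finite(L) & L > 0, 1 / L, 0)
  Ew <- sum(inv) / (N * (N - 1))
  s <- rowSums(W)
  a <- c(s[edges[, 1]], s[edges[, 2]])
  b <- c(s[edges[, 2]], s[edges[, 1]])
  rw <- if (K >= 2 && sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
  list(rw = rw, Tw = Tw, D = D, Ew = Ew)
}

randomGraphMatrix <- function(n, pEdge = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < pEdge) W[i, j] <- W[j, i] <- runif(1, 0.1, 1)
  W
}

adjacencyToGraph <- function(W) {
  labels <- paste0("n", seq_len(nrow(W)))
  mask <- W > 0
  diag(mask) <- FALSE
  rho <- W
  rho[!mask] <- NA_real_
  diag(rho) <- 1
  dimnames(rho) <- dimnames(mask) <- list(labels, labels)
  ne <- (mask) * 1
  m <- new("ConnectivityMatrix", labels = labels, rho = rho, mask = mask,
           nEff = ne)
  toNetwork(m, "abs")
}

# --- L1 regression oracle ---------------------------------------------------

# exact minimum of the L1 objective over all p-point exact-fit candidates
# (an L1 optimum always interpolates p points in general position)
bruteL1 <- function(X, y) {
  p <- ncol(X)
  best <- NULL
  bestLoss <- Inf
  for (ix in utils::combn(nrow(X), p, simplify = FALSE)) {
    Xi <- X[ix, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- solve(Xi, y[ix])
    loss <- sum(abs(y - X %*% b))
    if (loss < bestLoss - 1e-12) {
      bestLoss <- loss
      best <- b
    }
  }
  list(coef = best, loss = bestLoss)
}

# --- fixtures ---------------------------------------------------------------

# short protocol for fast unit tests (>= 5 blocks for the gate)
tinyProtocol <- function(seed = 1L, color = "red", nBlocks = 6L)
  generateProtocol(seed, nBlocks = nBlocks, onDuration = 20,
                   offRange = c(17, 27), baseline = 60, recovery = 40,
                   color = color)

# a 2-Hz Recording built directly from a signal matrix (signals x samples)
makeRecording2Hz <- function(mat, timelineObj = NULL) {
  ch <- lapply(seq_len(nrow(mat)), function(i)
    list(samples = mat[i, ], fs = 2, units = "au"))
  names(ch) <- rownames(mat)
  new("Recording", channels = ch, timeline = timelineObj)
}

# normalized TrialBlock with given signal rows (signals x 70 at 2 Hz)
makeBlock <- function(mat, onset = 100, normalized = FALSE) {
  b <- new("TrialBlock", segment = mat, onsetTime = onset, fs = 2)
  if (normalized) b <- normalizeDetrend(b)
  b
}

# synthetic SubjectResult with one pooled channel pair and given stimulus
# response value(s)
makeSubjectResult <- function(y, id, color = "red", age = 30,
                              gender = "male", weight = 1,
                              signals = c("X_L", "X_R")) {
  y <- rep_len(y, length(signals))
  ba <- matrix(0, length(signals), 7, dimnames = list(signals, NULL))
  ba[, 2:5] <- y
  h <- stats::setNames(rep(weight > 0, length(signals)), signals)
  new("SubjectResult", blockAverage = ba,
      pvals = matrix(0.5, length(signals), 4,
                     dimnames = list(signals, NULL)),
      h = h, weight = stats::setNames(as.numeric(h), signals),
      covariates = list(color = color, age = age, gender = gender),
      subjectId = id)
}

# offset-aligned residual of a corrected signal against its clean oracle:
# per run of the given mask complement, the median offset is removed
alignResidual <- function(corrected, clean, mask) {
  resid <- corrected - clean
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lastOffset <- 0
  for (k in seq_along(r$values)) {
    idx <- starts[k]:ends[k]
    if (!r$values[k]) {
      lastOffset <- median(resid[idx])
      resid[idx] <- resid[idx] - lastOffset
    } else {
      resid[idx] <- resid[idx] - lastOffset
    }
  }
  resid
}
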