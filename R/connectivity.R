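#' @include AllClasses.R stats-tests.R block.R
NULL

#' Per-trial Spearman connectivity matrix with significance mask
#'
#' Spearman rank correlation of every unordered signal pair over the
#' within-trial samples of one (normalized) trial segment, with two-sided
#' p-values (t approximation on the rank correlation), Benjamini-Hochberg
#' FDR correction across all pairs, and deletion (masking) of the
#' nonsignificant entries. Constant (zero-variance) signals have all their
#' pairs masked, with a warning.
#'
#' @param block a normalized [TrialBlock-class] carrying all signals
#' @param alpha FDR level (default 0.05)
#' @param minPairs minimal complete pairs per entry (default 10)
#' @return a [ConnectivityMatrix-class]
#' @export
trialCorrelationMatrix <- function(block, alpha = 0.05, minPairs = 10L) {
  seg <- t(block@segment)             # samples x signals
  labels <- colnames(seg)
  p <- ncol(seg)
  # midrank transform per signal, then Pearson on ranks = Spearman
  rk <- apply(seg, 2L, function(col) {
    out <- rep(NA_real_, length(col))
    ok <- !is.na(col)
    out[ok] <- rank(col[ok])
    out
  })
  rho <- suppressWarnings(stats::cor(rk, use = "pairwise.complete.obs"))
  nEff <- crossprod(!is.na(rk))
  const <- apply(seg, 2L, function(col) {
    v <- col[!is.na(col)]
    length(v) < 2L || stats::var(v) == 0
  })
  if (any(const))
    warning("constant signal(s) masked: ",
            paste(labels[const], collapse = ", "))
  up <- upper.tri(rho)
  nv <- nEff[up]
  rv <- rho[up]
  tv <- rv * sqrt(pmax(nv - 2, 0) / pmax(1 - rv^2, 1e-300))
  pv <- 2 * pt(-abs(tv), df = pmax(nv - 2, 1))
  pv[abs(rv) >= 1 - 1e-12] <- 0        # perfectly monotone pairs
  bad <- is.na(rv) | nv < minPairs
  pv[bad] <- NA_real_
  keepUp <- fdrBH(pv, alpha) & !bad
  mask <- matrix(FALSE, p, p, dimnames = dimnames(rho))
  mask[up] <- keepUp
  mask <- mask | t(mask)
  diag(mask) <- FALSE                  # diagonal excluded by convention
  rhoOut <- rho
  rhoOut[!mask] <- NA_real_
  diag(rhoOut) <- 1
  ne <- matrix(0, p, p, dimnames = dimnames(rho))
  ne[mask] <- 1
  new("ConnectivityMatrix", labels = labels, rho = rhoOut, mask = mask,
      nEff = ne)
}

#' Average a stack of connectivity matrices
#'
#' Entrywise mean over the matrices in which the entry is unmasked
#' (contributing-matrices convention; \code{nEff} records the counts), or
#' over all matrices treating deleted entries as zero
#' (\code{deletedAsZero = TRUE}). Entries unmasked in no matrix stay
#' masked. The stack order is irrelevant.
#'
#' @param stack list of [ConnectivityMatrix-class] with identical labels
#' @param deletedAsZero treat deleted entries as zero instead of excluding
#'   them (default FALSE)
#' @return the averaged [ConnectivityMatrix-class]
#' @export
averageMatrices <- function(stack, deletedAsZero = FALSE) {
  stopIfNot(length(stack) >= 1L, "empty stack")
  labels <- stack[[1L]]@labels
  for (m in stack)
    stopIfNot(identical(m@labels, labels), "label sets differ")
  p <- length(labels)
  sum <- matrix(0, p, p)
  cnt <- matrix(0, p, p)
  for (m in stack) {
    v <- m@rho
    v[!m@mask] <- 0
    diag(v) <- 0
    sum <- sum + v
    cnt <- cnt + m@mask
  }
  denom <- if (deletedAsZero) length(stack) else pmax(cnt, 1)
  avg <- sum / denom
  mask <- cnt > 0
  avg[!mask] <- NA_real_
  diag(avg) <- 1
  dimnames(avg) <- list(labels, labels)
  dimnames(mask) <- list(labels, labels)
  cntd <- cnt
  dimnames(cntd) <- list(labels, labels)
  new("ConnectivityMatrix", labels = labels, rho = avg, mask = mask,
      nEff = cntd)
}

#' Transform a connectivity matrix into a weighted undirected graph
#'
#' One node per label; one edge per unmasked off-diagonal entry. The
#' default weight transform takes the absolute correlation (the weighted
#' network metrics require nonnegative weights); "positive" keeps only
#' positive correlations.
#'
#' @param matrixObj a [ConnectivityMatrix-class]
#' @param weightTransform "abs" (default) or "positive"
#' @return an [igraph::graph] with a \code{weight} edge attribute in (0, 1]
#' @export
toNetwork <- function(matrixObj, weightTransform = c("abs", "positive")) {
  weightTransform <- match.arg(weightTransform)
  labels <- matrixObj@labels
  rho <- matrixObj@rho
  mask <- matrixObj@mask
  up <- which(upper.tri(rho) & mask, arr.ind = TRUE)
  w <- rho[cbind(up[, 1L], up[, 2L])]
  if (weightTransform == "abs") w <- abs(w)
  keep <- !is.na(w) & w > 0
  up <- up[keep, , drop = FALSE]
  w <- pmin(w[keep], 1)
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(up))
    g <- igraph::add_edges(g, t(cbind(up[, 1L], up[, 2L])),
                           weight = w)
  g
}

#' Weighted complex-network metrics
#'
#' Computes the four weighted network summaries of a connectivity graph:
#' \describe{
#'   \item{D}{density, \code{2K / (N (N - 1))} for K edges and N nodes.}
#'   \item{Tw}{weighted transitivity: the sum over connected triples of
#'     geometric-mean triangle weights divided by the number of connected
#'     triples \code{sum k_i (k_i - 1)}, with weights pre-scaled by the
#'     maximum weight.}
#'   \item{Ew}{weighted global efficiency: mean over ordered node pairs of
#'     the inverse shortest path length, with edge lengths \code{1/w};
#'     disconnected pairs contribute 0.}
#'   \item{rw}{weighted assortativity: Pearson correlation of endpoint
#'     node strengths over edges, both orientations; endpoint strengths
#'     include the connecting edge. NA (flagged) when fewer than 2 edges
#'     or the endpoint strengths are constant.}
#' }
#'
#' @param g a weighted undirected igraph graph
#' @return a [NetworkMetrics-class]
#' @export
networkMetrics <- function(g) {
  N <- igraph::vcount(g)
  if (N < 2L) stop("graph must have at least 2 nodes", call. = FALSE)
  K <- igraph::ecount(g)
  D <- 2 * K / (N * (N - 1))
  if (K == 0L)
    return(new("NetworkMetrics", rw = NA_real_, Tw = 0, D = 0, Ew = 0))
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  ## transitivity (weights scaled by the maximum weight)
  Ws <- W / max(W)
  Wroot <- Ws^(1 / 3)
  cyc <- diag(Wroot %*% Wroot %*% Wroot)        # 2 x weighted triangles per node
  k <- rowSums(W > 0)
  denom <- sum(k * (k - 1))
  Tw <- if (denom > 0) sum(cyc) / denom else 0
  ## efficiency: shortest paths over lengths 1/w
  dmat <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / dmat
  diag(inv) <- 0
  inv[is.infinite(dmat)] <- 0
  Ew <- sum(inv) / (N * (N - 1))
  ## assortativity over edge endpoint strengths (both orientations)
  s <- rowSums(W)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- c(s[el[, 1L]], s[el[, 2L]])
  b <- c(s[el[, 2L]], s[el[, 1L]])
  rw <- if (K >= 2L && stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::cor(a, b) else NA_real_
  new("NetworkMetrics", rw = rw, Tw = Tw, D = D, Ew = Ew)
}

#' Compare network metrics between colors
#'
#' Two-sided Wilcoxon rank-sum tests of each network metric between every
#' pair of colors, with one value per subject per color as the sampling
#' unit. Exact p-values for small samples; ties midranked.
#'
#' @param metricsPerColor named list (one element per color) of lists of
#'   [NetworkMetrics-class], one per subject
#' @return data.frame with columns metric, color1, color2, p
#' @export
compareColors <- function(metricsPerColor) {
  colors <- names(metricsPerColor)
  stopIfNot(length(colors) >= 2L, "at least two colors required")
  for (cc in colors)
    stopIfNot(length(metricsPerColor[[cc]]) >= 3L,
              "at least 3 subjects per color required")
  vals <- lapply(metricsPerColor, function(lst)
    do.call(rbind, lapply(lst, as.numeric)))
  rows <- list()
  for (m in c("rw", "Tw", "D", "Ew")) {
    for (i in seq_len(length(colors) - 1L)) {
      for (j in (i + 1L):length(colors)) {
        x <- vals[[i]][, m]; y <- vals[[j]][, m]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        p <- if (length(x) && length(y)) wilcoxonRankSum(x, y) else NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(metric = m, color1 = colors[i], color2 = colors[j],
                     p = p, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
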