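mkConnBlock <- function(mat) {
  b <- new("TrialBlock", segment = mat, onsetTime = 10, fs = 2)
  b@normalized <- TRUE
  b
}

test_that("Spearman matrices capture monotone association and mask the rest", {
  t <- seq_len(70)
  x <- as.numeric(t)
  mat <- rbind(A = x, B = 2 * x + 1, C = -x^3)
  cm <- trialCorrelationMatrix(mkConnBlock(mat))
  expect_equal(cm@rho["A", "B"], 1)
  expect_equal(cm@rho["A", "C"], -1)
  expect_true(all(cm@mask[upper.tri(cm@mask)]))
  # hand-ranked example on 5 points: d^2 = (0,1,1,1,1), rs = 1 - 6*4/(5*24)
  seg5 <- rbind(X = c(1, 2, 3, 4, 5), Y = c(1, 3, 2, 5, 4))
  rho5 <- suppressWarnings(stats::cor(seg5["X", ], seg5["Y", ],
                                      method = "spearman"))
  expect_equal(rho5, 1 - 6 * 4 / (5 * 24))
  # implementation agrees with cor.test across random pairs
  set.seed(30)
  for (i in 1:10) {
    m <- rbind(A = rnorm(70), B = rnorm(70))
    cm2 <- trialCorrelationMatrix(mkConnBlock(m), alpha = 1)
    ct <- suppressWarnings(stats::cor.test(m[1, ], m[2, ],
                                           method = "spearman"))
    expect_equal(cm2@rho["A", "B"], unname(ct$estimate), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  m <- rbind(A = rnorm(70), B = rnorm(70))
  r0 <- trialCorrelationMatrix(mkConnBlock(m), alpha = 1)@rho["A", "B"]
  m2 <- rbind(A = exp(m["A", ]), B = atan(m["B", ]))
  r1 <- trialCorrelationMatrix(mkConnBlock(m2), alpha = 1)@rho["A", "B"]
  expect_equal(r0, r1)
  # constant signal: pairs masked with a warning
  mc <- rbind(A = rnorm(70), B = rep(1, 70))
  expect_warning(cmc <- trialCorrelationMatrix(mkConnBlock(mc)),
                 "constant")
  expect_false(cmc@mask["A", "B"])
})

test_that("matrix averaging follows the contributing-entries convention", {
  mk <- function(rhoAB, masked = FALSE) {
    labels <- c("A", "B", "C")
    rho <- diag(3); rho[] <- NA; diag(rho) <- 1
    mask <- matrix(FALSE, 3, 3)
    if (!masked) {
      rho[1, 2] <- rho[2, 1] <- rhoAB
      mask[1, 2] <- mask[2, 1] <- TRUE
    }
    dimnames(rho) <- dimnames(mask) <- list(labels, labels)
    new("ConnectivityMatrix", labels = labels, rho = rho, mask = mask,
        nEff = mask * 1)
  }
  one <- averageMatrices(list(mk(0.4)))
  expect_equal(one@rho["A", "B"], 0.4)
  two <- averageMatrices(list(mk(0.2), mk(0.6)))
  expect_equal(two@rho["A", "B"], 0.4)
  # masked in one matrix: average over the contributing matrix only
  mixed <- averageMatrices(list(mk(0.4), mk(0, masked = TRUE)))
  expect_equal(mixed@rho["A", "B"], 0.4)
  expect_equal(mixed@nEff["A", "B"], 1)
  # treat-deleted-as-zero alternative
  mixed0 <- averageMatrices(list(mk(0.4), mk(0, masked = TRUE)),
                            deletedAsZero = TRUE)
  expect_equal(mixed0@rho["A", "B"], 0.2)
  # permutation invariance
  set.seed(31)
  ms <- lapply(runif(4, -1, 1), mk)
  a1 <- averageMatrices(ms)
  a2 <- averageMatrices(rev(ms))
  expect_equal(a1@rho, a2@rho)
})

test_that("the network transform maps unmasked entries to weighted edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- -0.8
  g <- adjacencyToGraph(abs(W))
  expect_equal(igraph::ecount(g), 1)
  # negative correlation under abs transform -> weight 0.8
  labels <- c("A", "B")
  rho <- matrix(c(1, -0.8, -0.8, 1), 2, dimnames = list(labels, labels))
  mask <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2,
                 dimnames = list(labels, labels))
  cm <- new("ConnectivityMatrix", labels = labels, rho = rho, mask = mask,
            nEff = mask * 1)
  g2 <- toNetwork(cm, "abs")
  expect_equal(igraph::E(g2)$weight, 0.8)
  gPos <- toNetwork(cm, "positive")
  expect_equal(igraph::ecount(gPos), 0)
  # fully masked: edgeless
  maskN <- matrix(FALSE, 2, 2, dimnames = list(labels, labels))
  rhoN <- rho; rhoN[!maskN] <- NA; diag(rhoN) <- 1
  cmN <- new("ConnectivityMatrix", labels = labels, rho = rhoN,
             mask = maskN, nEff = maskN * 1)
  expect_equal(igraph::ecount(toNetwork(cmN)), 0)
})

test_that("network metrics match closed-form cases", {
  # complete unit-weight triangle saturates everything
  W3 <- matrix(1, 3, 3); diag(W3) <- 0
  m3 <- networkMetrics(adjacencyToGraph(W3))
  expect_equal(m3@D, 1); expect_equal(m3@Tw, 1); expect_equal(m3@Ew, 1)
  # two-edge unit star
  Ws <- matrix(0, 3, 3)
  Ws[1, 2] <- Ws[2, 1] <- 1; Ws[2, 3] <- Ws[3, 2] <- 1
  ms <- networkMetrics(adjacencyToGraph(Ws))
  expect_equal(ms@D, 2 / 3); expect_equal(ms@Tw, 0)
  expect_equal(ms@rw, -1)
  # two nodes, single edge 0.5: Ew = 0.5
  W2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(networkMetrics(adjacencyToGraph(W2))@Ew, 0.5)
  # empty graph errors; single-node graphs error
  expect_error(networkMetrics(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2 nodes")
})

test_that("network metrics agree with brute-force evaluation on random graphs", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    W <- randomGraphMatrix(n)
    got <- networkMetrics(adjacencyToGraph(W))
    exp <- bruteNetworkMetrics(W)
    expect_equal(got@D, exp$D, tolerance = 1e-12)
    expect_equal(got@Tw, exp$Tw, tolerance = 1e-12)
    expect_equal(got@Ew, exp$Ew, tolerance = 1e-12)
    if (is.na(exp$rw)) expect_true(is.na(got@rw))
    else expect_equal(got@rw, exp$rw, tolerance = 1e-12)
  }
})

test_that("between-color comparisons use the exact rank-sum test", {
  mkMet <- function(v) new("NetworkMetrics", rw = v, Tw = v, D = v, Ew = v)
  same <- list(red = lapply(c(1, 2, 3, 4, 5) / 10, mkMet),
               blue = lapply(c(1, 2, 3, 4, 5) / 10, mkMet))
  tab <- compareColors(same)
  expect_true(all(tab$p == 1))
  sep <- list(red = lapply(1:5 / 10, mkMet),
              blue = lapply(6:10 / 10, mkMet))
  tab2 <- compareColors(sep)
  expect_equal(unique(tab2$p), 2 / 252)
  expect_error(compareColors(list(red = lapply(c(0.1, 0.2), mkMet),
                                  blue = lapply(1:5 / 10, mkMet))),
               "3 subjects")
})

test_that("a shared latent driver produces an unmasked strong pair", {
  set.seed(33)
  found <- 0L
  for (r in 1:5) {
    mats <- lapply(1:10, function(k) {
      latent <- rnorm(70)
      seg <- rbind(HR = latent + 0.3 * rnorm(70),
                   MAP = latent + 0.3 * rnorm(70),
                   SCL = rnorm(70),
                   PTT = rnorm(70))
      trialCorrelationMatrix(mkConnBlock(seg))
    })
    avg <- averageMatrices(mats)
    if (avg@mask["HR", "MAP"] && avg@rho["HR", "MAP"] > 0.6 &&
        avg@nEff["HR", "MAP"] == 10)
      found <- found + 1L
  }
  expect_gte(found, 4L)
})
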