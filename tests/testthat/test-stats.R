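test_that("signed-rank p-values match exhaustive sign-flip enumeration", {
  # closed cases
  expect_equal(wilcoxonSignedRank(1:15), 2 / 2^15)
  expect_equal(wilcoxonSignedRank(c(1, -1, 2, -2, 3, -3)), 1)
  x6 <- c(1, 2, 3, 4, 5, -6)
  expect_equal(wilcoxonSignedRank(x6), bruteSignedRank(x6))
  # random cases incl. ties and zeros, n 5..10
  set.seed(10)
  for (i in 1:60) {
    n <- sample(5:10, 1)
    x <- sample(c(-4:4), n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)
    if (sum(x != 0) < 5) next
    expect_equal(wilcoxonSignedRank(x), bruteSignedRank(x),
                 info = paste(x, collapse = ","))
  }
  # n < 5 nonzero: p = 1 by convention; empty input errors
  expect_equal(wilcoxonSignedRank(c(1, 2, 3, 0, 0)), 1)
  expect_error(wilcoxonSignedRank(numeric()), "empty")
  # no-ties case agrees with the reference implementation
  set.seed(11)
  x <- rnorm(12)
  expect_equal(wilcoxonSignedRank(x),
               stats::wilcox.test(x, exact = TRUE)$p.value)
})

test_that("rank-sum p-values match exact subset enumeration", {
  expect_equal(wilcoxonRankSum(1:5, 6:10), 2 / 252)
  expect_equal(wilcoxonRankSum(rep(3, 4), rep(3, 4)), 1)
  set.seed(12)
  for (i in 1:40) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- sample(0:5, nx, replace = TRUE)
    y <- sample(0:5, ny, replace = TRUE)
    expect_equal(wilcoxonRankSum(x, y), bruteRankSum(x, y),
                 info = paste(c(x, "|", y), collapse = ","))
  }
  x <- rnorm(8); y <- rnorm(7)
  expect_equal(wilcoxonRankSum(x, y),
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("FDR rejection flags follow the step-up rule and are monotone", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.5)), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdrBH(rep(1, 6)), rep(FALSE, 6))
  expect_equal(fdrBH(0.04), TRUE)
  # agreement with p.adjust threshold and monotonicity in each p
  set.seed(13)
  for (i in 1:30) {
    p <- runif(8)
    r1 <- fdrBH(p)
    j <- sample(8, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    r2 <- fdrBH(p2)
    expect_true(all(r2[r1] | !r1[r1]))  # no rejection lost
    expect_true(all(r1 == (p.adjust(p, "BH") <= 0.05)))
  }
})

test_that("the quantile solver minimizes the L1 objective", {
  set.seed(14)
  # noiseless exact fit at any quantile
  age <- runif(10, 20, 60)
  X <- cbind(1, age)
  y <- 2 + 3 * age
  b <- fitQuantile(X, y)
  expect_equal(unname(b), c(2, 3), tolerance = 1e-8)
  # random small problems vs exact enumeration oracle
  for (i in 1:20) {
    n <- sample(7:10, 1)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n)
    b <- fitQuantile(X, y)
    oracle <- bruteL1(X, y)
    lossGot <- sum(abs(y - X %*% b))
    expect_lte(lossGot, oracle$loss + 1e-6 * (1 + oracle$loss))
  }
  # intercept-only path is the sample median
  y <- c(4, 1, 7, 2, 9)
  expect_equal(unname(fitQuantile(matrix(1, 5, 1), y)), median(y))
})

test_that("the group model honors weights, contrasts and preconditions", {
  # noiseless covariate recovery with all weights 1
  set.seed(15)
  res <- lapply(1:8, function(i)
    makeSubjectResult(2 + 3 * (20 + i), sprintf("S%02d", i), age = 20 + i,
                      gender = if (i %% 2) "male" else "female"))
  gm <- groupQuantileRegression(res, c("X_L", "X_R"), terms = "age",
                                nBoot = 50, seed = 1)
  expect_equal(unname(gm@coefficients), c(2, 3), tolerance = 1e-6)
  expect_true(all(gm@ci[1, ] <= gm@coefficients + 1e-8))
  expect_true(all(gm@ci[2, ] >= gm@coefficients - 1e-8))
  # all weights zero: indeterminate
  res0 <- lapply(1:6, function(i)
    makeSubjectResult(rnorm(1), sprintf("S%02d", i), weight = 0))
  gm0 <- groupQuantileRegression(res0, c("X_L", "X_R"), nBoot = 50)
  expect_true(isIndeterminate(gm0))
  # single color with color term requested: degenerate design error
  expect_error(groupQuantileRegression(res, c("X_L", "X_R"),
                                       terms = "color", nBoot = 10),
               "color")
  # zero-weighted subjects enter as zeros by default and hold the median
  resMix <- c(lapply(1:10, function(i)
    makeSubjectResult(0.5 + rnorm(1, 0, 0.01), sprintf("A%02d", i),
                      weight = 0)),
    lapply(1:2, function(i)
      makeSubjectResult(0.8, sprintf("B%02d", i), weight = 1)))
  gmZ <- groupQuantileRegression(resMix, c("X_L", "X_R"), nBoot = 200,
                                 seed = 2)
  expect_equal(unname(gmZ@coefficients[1]), 0, tolerance = 1e-6)
  expect_false(gmZ@significant[[1]])
  gmE <- groupQuantileRegression(resMix, c("X_L", "X_R"), nBoot = 200,
                                 seed = 2, zeroWeight = "exclude")
  expect_equal(unname(gmE@coefficients[1]), 0.8, tolerance = 1e-6)
})

test_that("color contrasts recover a blue-only effect in a synthetic cohort", {
  # cohort-level parameter recovery: effect 0.5 under blue only,
  # noise SD 0.2, 14 subjects; blue-vs-red contrast recovered
  set.seed(16)
  hits <- 0L
  nRep <- 20L
  for (r in seq_len(nRep)) {
    res <- list()
    for (i in 1:14) {
      for (color in c("red", "green", "blue")) {
        eff <- if (color == "blue") 0.5 else 0
        res[[paste(i, color)]] <-
          makeSubjectResult(eff + rnorm(2, 0, 0.2), sprintf("S%02d", i),
                            color = color, age = 20 + i,
                            gender = if (i %% 2) "male" else "female")
      }
    }
    gm <- groupQuantileRegression(res, c("X_L", "X_R"),
                                  terms = c("color", "age", "gender"),
                                  nBoot = 400, seed = r)
    hits <- hits + gm@significant[["colorblue"]]
  }
  expect_gte(hits / nRep, 0.9)
})
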