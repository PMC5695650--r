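#' @importFrom stats rnorm runif fft median sd approx quantile complete.cases
#' @importFrom stats dgamma pt p.adjust smooth.spline predict loess splinefun
NULL

# Evaluate `expr` under a local, restored RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed (< 2^31) from a base seed and a stream index.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629)
}

# 1/f (pink) noise with unit standard deviation, via spectral shaping.
# k independent channels are generated pairwise with one complex FFT per
# pair (the spectral shaping is a real even filter, so the real and
# imaginary parts remain independent after shaping).
pinkNoiseK <- function(n, k = 1L, seed = NULL) {
  gen <- function() {
    m <- stats::nextn(max(n, 2L), c(2L, 3L, 5L))
    f <- seq_len(m) - 1L
    f <- pmin(f, m - f)          # two-sided frequency index
    scale <- 1 / sqrt(pmax(f, 1))
    scale[1L] <- 0               # remove DC
    out <- matrix(0, n, k)
    j <- 1L
    while (j <= k) {
      pair <- j < k
      z <- if (pair) complex(real = rnorm(m), imaginary = rnorm(m))
           else as.complex(rnorm(m))
      x <- fft(fft(z) * scale, inverse = TRUE) / m
      xr <- Re(x)[seq_len(n)]
      out[, j] <- xr / sd(xr)
      if (pair) {
        xi <- Im(x)[seq_len(n)]
        out[, j + 1L] <- xi / sd(xi)
      }
      j <- j + 2L
    }
    out
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

pinkNoise <- function(n, seed = NULL) as.vector(pinkNoiseK(n, 1L, seed))

# Band-limited slow gaussian drift with SD `scale` (first-order smoothed walk).
slowDrift <- function(n, fs, scale, cutoff = 0.01) {
  if (scale <= 0 || n < 4L) return(numeric(n))
  alpha <- exp(-2 * pi * cutoff / fs)
  x <- stats::filter(rnorm(n), alpha, method = "recursive")
  x <- as.numeric(x)
  s <- sd(x)
  if (s > 0) x * (scale / s) else x
}

# Moving standard deviation with a centered window of w samples (w >= 2);
# edges use shrinking windows.
movingSD <- function(x, w) {
  w <- max(2L, as.integer(w))
  rollingSDCpp(x, w %/% 2L)
}

# Analytic-signal envelope (discrete Hilbert transform via FFT).
hilbertEnvelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}



# Contiguous runs of TRUE in a logical vector -> matrix of (start, end).
logicalRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Median that returns NA (not an error) on all-NA input, dropping NAs.
medianNA <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else median(x)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
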