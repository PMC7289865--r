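# Internal helpers: seeded substreams, coloured noise, peak prominence.

# Derive a reproducible substream seed from a master seed and a stream
# index; kept inside 32-bit signed range (Lehmer-style multiplicative hash).
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

withSubSeed <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(subSeed(seed, k))
  force(expr)
}

# 1/f ("pink") noise via spectral shaping of white noise; unit SD.
pinkNoise <- function(n) {
  if (n < 2) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Smooth low-frequency noise (random walk low-passed), unit SD.
driftNoise <- function(n, smooth = 25) {
  x <- cumsum(stats::rnorm(n))
  k <- min(smooth, n)
  x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  x[is.na(x)] <- 0
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else (x - mean(x)) / s
}

# Topographic prominence of the peak at index i: height above the higher
# of the two minima separating it from the nearest higher terrain (or the
# series end).
peakProminence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  left <- h
  j <- i - 1L
  lo <- h
  while (j >= 1L) {
    if (x[j] > h) break
    if (x[j] < lo) lo <- x[j]
    j <- j - 1L
  }
  left <- lo
  lo <- h
  j <- i + 1L
  while (j <= n) {
    if (x[j] > h) break
    if (x[j] < lo) lo <- x[j]
    j <- j + 1L
  }
  right <- lo
  h - max(left, right)
}

# Local maxima indices (strict rise, plateau-tolerant fall).
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# Linear-interpolation resampling of all columns of a channel matrix at
# (possibly warped) sample times given in units of the original index.
resampleChannels <- function(ch, at) {
  n <- nrow(ch)
  at <- pmin(pmax(at, 1), n)
  out <- apply(ch, 2, function(col) stats::approx(seq_len(n), col, xout = at)$y)
  colnames(out) <- colnames(ch)
  out
}

sampleSD <- function(x) stats::sd(x)
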