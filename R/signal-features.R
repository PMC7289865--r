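#' @useDynLib coaStar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Dominant spectral resonance of a movement signal
#'
#' Estimates the resonant frequency (RF) and the spectral magnitude at
#' resonance (MR) of a uniformly sampled signal: the series is
#' mean-removed, Hann-windowed, and the periodogram peak above DC is
#' located.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @return list with \code{rf} (Hz) and \code{mr} (linear spectral
#'   magnitude at \code{rf}).
#' @examples
#' t <- seq(0, 10, by = 1 / 50)
#' resonanceProfile(sin(2 * pi * 2 * t), 50)$rf  # 2 Hz
#' @export
resonanceProfile <- function(x, fs) {
  if (fs <= 0) stop("fs must be positive")
  n <- length(x)
  if (n < 2 * fs) stop("need at least 2 seconds of samples")
  x <- x - mean(x)
  if (all(x == 0)) stop("resonance undefined for a constant series")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)) # Hann
  X <- stats::fft(x * w)
  half <- seq(2L, floor(n / 2) + 1L) # strictly above DC
  mag <- Mod(X[half]) / n
  i <- which.max(mag)
  list(rf = (half[i] - 1L) * fs / n, mr = mag[i])
}

#' Sample entropy and multiscale entropy
#'
#' \code{sampleEntropy} is the classic conditional-probability regularity
#' statistic: the negative log of the ratio of template matches at length
#' m + 1 to matches at length m, with Chebyshev distance and tolerance r;
#' self-matches are excluded. \code{multiscaleEntropy} coarse-grains the
#' series by non-overlapping means of s samples per scale s and applies
#' sample entropy with tolerance fixed at \code{r_frac} times the SD of
#' the original (scale-1) series.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance (absolute units).
#' @param r_frac tolerance as a fraction of the SD of \code{x}
#'   (default 0.15).
#' @param scales integer scales (default 1:5).
#' @return \code{sampleEntropy}: a single nonnegative value (nats; 0 for
#'   a constant series, NA when no template matches exist).
#'   \code{multiscaleEntropy}: named vector of entropies per scale; a
#'   scale whose coarse-grained series is shorter than 10 (m + 1) samples
#'   is reported NA.
#' @export
sampleEntropy <- function(x, m = 2, r) {
  if (r <= 0) stop("tolerance r must be positive")
  n <- length(x)
  if (n <= m + 1) stop("series too short for template length m")
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r))
  B <- cnt[1]
  A <- cnt[2]
  if (is.na(B) || B == 0) return(NA_real_)
  if (A == 0) return(NA_real_)
  -log(A / B)
}

#' @rdname sampleEntropy
#' @export
multiscaleEntropy <- function(x, m = 2, r_frac = 0.15, scales = 1:5) {
  sdx <- stats::sd(x)
  if (sdx == 0) {
    out <- rep(0, length(scales)) # every template matches trivially
    names(out) <- paste0("scale", scales)
    return(out)
  }
  r <- r_frac * sdx
  out <- vapply(scales, function(s) {
    ncg <- floor(length(x) / s)
    if (ncg < 10 * (m + 1)) return(NA_real_)
    cg <- colMeans(matrix(x[seq_len(ncg * s)], nrow = s))
    e <- sampleEntropy(cg, m = m, r = r)
    if (is.na(e)) NA_real_ else e
  }, numeric(1))
  names(out) <- paste0("scale", scales)
  out
}

#' Fuzzy entropy of a series
#'
#' Regularity statistic with a soft template-similarity membership:
#' templates are baseline-removed (mean-centred) and pairs contribute
#' exp(-(d / r)^n_exp) of their Chebyshev distance d. The entropy is the
#' negative log ratio of the mean membership at length m + 1 to that at
#' length m.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance; must be positive.
#' @param n_exp gradient exponent of the fuzzy membership (default 2).
#' @return nonnegative entropy (nats); 0 for a constant series.
#' @export
fuzzyEntropy <- function(x, m = 2, r, n_exp = 2) {
  if (r <= 0) stop("tolerance r must be positive")
  if (length(x) <= m + 1) stop("series too short for template length m")
  phi <- .fuzzyen_phi_cpp(as.numeric(x), as.integer(m), as.numeric(r),
                          as.numeric(n_exp))
  if (anyNA(phi) || phi[1] <= 0) return(NA_real_)
  max(0, -log(phi[2] / phi[1]))
}

#' Rhythmic variation of an event train
#'
#' Coefficient of variation (sample SD / mean) of the successive
#' inter-event intervals; dimensionless and invariant to time rescaling.
#'
#' @param event_times strictly increasing event times.
#' @return the CV of the inter-event intervals.
#' @export
rhythmicVariation <- function(event_times) {
  if (length(event_times) < 3) stop("need at least 3 events")
  iv <- diff(sort(event_times))
  stats::sd(iv) / mean(iv)
}

#' Detect movement/syllable events in a signal
#'
#' Local maxima whose topographic prominence exceeds a fraction of the
#' largest prominence in the series, with a minimum separation enforced
#' (the more prominent peak wins).
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param min_separation minimum inter-event time in seconds.
#' @param prominence_frac adaptive threshold as a fraction of the maximum
#'   peak prominence (default 0.3).
#' @return event times in seconds (possibly empty).
#' @export
detectEvents <- function(x, fs, min_separation = 0.15, prominence_frac = 0.3) {
  idx <- localMaxima(x)
  if (length(idx) == 0) return(numeric(0))
  prom <- vapply(idx, function(i) peakProminence(x, i), numeric(1))
  if (max(prom) <= 0) return(numeric(0))
  keep <- prom >= prominence_frac * max(prom)
  idx <- idx[keep]
  prom <- prom[keep]
  # enforce separation, keeping the more prominent peak
  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  min_gap <- min_separation * fs
  for (i in ord) {
    if (all(abs(idx[i] - idx[chosen]) >= min_gap)) chosen <- c(chosen, i)
  }
  sort(idx[chosen]) / fs
}

#' Dynamic-time-warping alignment error
#'
#' Classic dynamic-programming DTW between two sequences with
#' absolute-difference local cost, full alignment and no warping window;
#' returns the accumulated cost of the optimal monotone path.
#'
#' @param a,b numeric sequences.
#' @return nonnegative alignment cost (0 for identical sequences).
#' @export
dtwError <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sequence")
  .dtw_cost_cpp(as.numeric(a), as.numeric(b))
}

#' Comprehensive response delay between marker and target
#'
#' The lag maximising the cross-correlation between the tracked marker
#' and the target trajectory, in seconds; positive values mean the marker
#' lags the target.
#'
#' @param marker,target equal-length series.
#' @param fs sampling rate (Hz).
#' @param max_lag maximum lag searched, in seconds (default 2).
#' @return delay in seconds.
#' @export
comprehensiveDelay <- function(marker, target, fs, max_lag = 2) {
  n <- length(marker)
  if (length(target) != n) stop("marker and target must have equal length")
  if (n < 2 * fs) stop("need at least 2 seconds of samples")
  if (stats::sd(marker) == 0 || stats::sd(target) == 0) {
    stop("delay undefined for a constant input")
  }
  L <- min(floor(max_lag * fs), n - 2)
  cc <- stats::ccf(marker, target, lag.max = L, plot = FALSE,
                   demean = TRUE)
  # ccf lag k correlates marker[t + k] with target[t]; the marker lagging
  # the target by d samples shows up at k = +d
  cc$lag[which.max(cc$acf)] / fs
}

#' Fitts-law index of performance
#'
#' log2(2 D / W) / MT in bits per second, for reach distance D, target
#' width W and movement time MT.
#'
#' @param D reach distance (> 0).
#' @param W target width (> 0).
#' @param MT movement time in seconds (> 0).
#' @return bits per second.
#' @export
indexOfPerformance <- function(D, W, MT) {
  if (any(c(D, W, MT) <= 0)) stop("D, W and MT must be positive")
  log2(2 * D / W) / MT
}

#' Directional changes of a trajectory
#'
#' Counts the sign changes of the second difference (acceleration
#' reversals) of a tracked coordinate, collapsing runs of zeros.
#'
#' @param x numeric series (length >= 3).
#' @return nonnegative integer count.
#' @export
directionalChanges <- function(x) {
  if (length(x) < 3) return(0L)
  d2 <- diff(x, differences = 2)
  # numerically zero second differences (e.g. a linear ramp) carry no
  # acceleration reversal
  d2[abs(d2) < 1e-9 * max(abs(x), 1)] <- 0
  s <- sign(d2)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Prosodic features of a repeated-syllable envelope
#'
#' From an audio amplitude envelope of repeated /ta/ utterances, detects
#' syllabic pulses by topographic prominence and computes six features:
#' \itemize{
#'   \item \code{duration_reg}: SD of per-syllable durations measured at
#'     50\% of each peak's prominence below the peak;
#'   \item \code{gap_reg}: SD of the gaps between consecutive syllable
#'     peaks;
#'   \item \code{peak_prominence}: mean topographic prominence;
#'   \item \code{compensation_reg}: SD of (peak height - prominence);
#'   \item \code{damping_ratio}: mean log-decrement damping ratio of each
#'     burst's decaying envelope above 75\% prominence;
#'   \item \code{rf}: mean within-burst resonant frequency on the wave
#'     data above 50\% prominence.
#' }
#'
#' @param envelope nonnegative amplitude envelope.
#' @param fs sampling rate (Hz).
#' @return named list of the six features plus \code{n_syllables}.
#' @export
speechFeatures <- function(envelope, fs) {
  ev <- detectEvents(envelope, fs, min_separation = 0.12,
                     prominence_frac = 0.35)
  if (length(ev) < 3) stop("fewer than 3 syllables detected")
  idx <- round(ev * fs)
  idx[idx < 1] <- 1
  prom <- vapply(idx, function(i) peakProminence(envelope, i), numeric(1))

  # syllable windows: midpoints between consecutive peaks (record edges at
  # the ends)
  n <- length(envelope)
  mids <- round((idx[-1] + idx[-length(idx)]) / 2)
  lo <- c(1L, mids + 1L)
  hi <- c(mids, n)

  durations <- numeric(length(idx))
  rfs <- rep(NA_real_, length(idx))
  zetas <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    win <- lo[k]:hi[k]
    seg <- envelope[win]
    # wave data at 50% prominence: the span of the burst above the level
    # half a prominence below the peak
    lev50 <- envelope[idx[k]] - 0.5 * prom[k]
    above <- which(seg >= lev50)
    if (length(above)) {
      span <- above[1]:above[length(above)]
      durations[k] <- length(span) / fs
      wav <- seg[span] - mean(seg[span])
      ns <- length(wav)
      if (ns >= 8 && any(wav != 0)) {
        X <- Mod(stats::fft(wav))[2:(floor(ns / 2) + 1)]
        rfs[k] <- which.max(X) * fs / ns
      }
    }
    # damping ratio: log decrement over the burst's successive oscillation
    # peaks extracted at 75% prominence
    lev75 <- envelope[idx[k]] - 0.75 * prom[k]
    pk <- localMaxima(seg)
    pk <- pk[seg[pk] >= lev75]
    if (length(pk) >= 2) {
      amp <- seg[pk]
      dec <- log(amp[-length(amp)] / amp[-1])
      dec <- dec[is.finite(dec) & dec > 0]
      if (length(dec)) {
        delta <- mean(dec)
        zetas[k] <- delta / sqrt(4 * pi^2 + delta^2)
      }
    }
  }
  gaps <- diff(ev)
  list(
    duration_reg = stats::sd(durations),
    gap_reg = stats::sd(gaps),
    peak_prominence = mean(prom),
    compensation_reg = stats::sd(envelope[idx] - prom),
    damping_ratio = mean(zetas, na.rm = TRUE),
    rf = mean(rfs, na.rm = TRUE),
    n_syllables = length(idx)
  )
}

#' Postural sway-velocity entropy features of a stance test
#'
#' Derives the sway velocity as the cumulative sum of the linearly
#' detrended trunk acceleration (per axis, divided by the sampling rate)
#' and computes its fuzzy entropy per axis, plus an "All" entropy of the
#' velocity magnitude.
#'
#' @param records list of \linkS4class{SignalRecord}s of the ROM test for
#'   one subject (conditions sensor front/back x eyes open/closed).
#' @param m,r_frac,n_exp fuzzy-entropy parameters; the tolerance is
#'   \code{r_frac} times the SD of each velocity series.
#' @param decimate keep every \code{decimate}-th velocity sample before
#'   the entropy (sway is low-frequency; default 2).
#' @return named vector over the 14 stance entropy features; conditions
#'   without a record are NA.
#' @export
swayEntropy <- function(records, m = 2, r_frac = 0.2, n_exp = 2,
                        decimate = 2L) {
  meta <- featureTaxonomy()
  ids <- meta$feature_id[meta$test == "ROM"]
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (rec in records) {
    if (rec@test != "ROM") next
    cond <- sprintf("%s_%s", rec@condition[["sensor"]], rec@condition[["eyes"]])
    ch <- rec@channels
    vel <- apply(ch[, c("acc_ml", "acc_ap", "acc_vt")], 2, function(a) {
      v <- cumsum(stats::resid(stats::lm(a ~ seq_along(a)))) / rec@fs
      v[seq(1, length(v), by = decimate)]
    })
    ent <- function(v) {
      s <- stats::sd(v)
      if (s == 0) return(0)
      fuzzyEntropy(v, m = m, r = r_frac * s, n_exp = n_exp)
    }
    out[sprintf("ROM_entropy_ML_%s", cond)] <- ent(vel[, 1])
    out[sprintf("ROM_entropy_AP_%s", cond)] <- ent(vel[, 2])
    out[sprintf("ROM_entropy_VT_%s", cond)] <- ent(vel[, 3])
    allId <- sprintf("ROM_entropy_All_%s", cond)
    if (allId %in% ids) {
      out[allId] <- ent(sqrt(rowSums(vel^2)))
    }
  }
  out
}
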