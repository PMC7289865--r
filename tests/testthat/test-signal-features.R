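test_that("resonance profile finds the dominant spectral peak", {
  t <- seq(1 / 50, 10, by = 1 / 50)
  expect_equal(resonanceProfile(sin(2 * pi * 2 * t), 50)$rf, 2, tolerance = 0.02)
  r <- resonanceProfile(0.5 * sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 3 * t), 50)
  expect_equal(r$rf, 3, tolerance = 0.02)
  expect_error(resonanceProfile(rep(1, 500), 50), "constant")
  expect_error(resonanceProfile(sin(1:10), 50), "2 seconds")
})

test_that("resonance peak agrees with a direct DFT periodogram", {
  fs <- 50
  t <- seq(1 / fs, 8, by = 1 / fs)
  for (s in 1:10) {
    set.seed(s)
    x <- sin(2 * pi * 1.5 * t) + 0.4 * coaStar:::pinkNoise(length(t))
    got <- resonanceProfile(x, fs)$rf
    want <- oracle_dft_peak(x, fs)
    # windowing may move the peak by at most one frequency bin
    expect_lte(abs(got - want), fs / length(x) + 1e-9)
  }
})

test_that("sample entropy matches the O(n^2) template-count oracle", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(80)
    r <- 0.2 * sd(x)
    expect_equal(sampleEntropy(x, m = 2, r = r), oracle_sampen(x, 2, r),
                 tolerance = 1e-12)
  }
  set.seed(99)
  x <- rnorm(100)
  expect_equal(sampleEntropy(x, m = 3, r = 0.3 * sd(x)),
               oracle_sampen(x, 3, 0.3 * sd(x)), tolerance = 1e-12)
})

test_that("multiscale entropy coarse-grains and handles degenerate input", {
  expect_equal(unname(multiscaleEntropy(rep(2, 300), scales = 1:3)),
               c(0, 0, 0))
  # iid noise is less regular than a short repeating pattern
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    noise <- rnorm(500)
    pattern <- rep_len(c(0, 1, 0, -1), 500) + 0.01 * rnorm(500)
    e_noise <- multiscaleEntropy(noise, scales = 1)[1]
    e_pat <- multiscaleEntropy(pattern, scales = 1)[1]
    wins <- wins + (e_noise > e_pat)
  }
  expect_gte(wins, 19)
  # short series at a large scale is reported missing
  expect_true(is.na(multiscaleEntropy(rnorm(50), scales = c(1, 10))[2]))
})

test_that("fuzzy entropy matches its brute-force oracle and is monotone in r", {
  for (s in 1:6) {
    set.seed(s)
    x <- rnorm(50)
    expect_equal(fuzzyEntropy(x, m = 2, r = 0.25, n_exp = 2),
                 oracle_fuzzyen(x, 2, 0.25, 2), tolerance = 1e-12)
  }
  set.seed(11)
  x <- rnorm(60)
  expect_equal(fuzzyEntropy(x, m = 2, r = 0.4, n_exp = 1.5),
               oracle_fuzzyen(x, 2, 0.4, 1.5), tolerance = 1e-12)
  vals <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.6),
                 function(r) fuzzyEntropy(x, m = 2, r = r), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_equal(fuzzyEntropy(rep(1, 50), m = 2, r = 0.2), 0)
  expect_error(fuzzyEntropy(x, m = 2, r = 0), "positive")
})

test_that("rhythmic variation is the CV of inter-event intervals", {
  expect_equal(rhythmicVariation(seq(0, 10, by = 0.5)), 0)
  # intervals (1, 1, 2): sample SD convention
  expect_equal(rhythmicVariation(c(0, 1, 2, 4)),
               sqrt(1 / 3) / (4 / 3), tolerance = 1e-12)
  expect_equal(rhythmicVariation(c(0, 1, 2, 4) * 3.7),
               rhythmicVariation(c(0, 1, 2, 4)), tolerance = 1e-12)
  expect_error(rhythmicVariation(c(0, 1)), "3 events")
})

test_that("event detection recovers pulse trains and their jitter", {
  fs <- 100
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- rep(0, length(t))
  centers <- seq(0.5, 9.5, by = 1)
  for (tc in centers) x <- x + exp(-((t - tc)^2) / (2 * 0.03^2))
  ev <- detectEvents(x, fs)
  expect_length(ev, 10)
  expect_true(all(abs(ev - centers) <= 1 / fs + 1e-9))
  expect_length(detectEvents(rep(0, 500), fs), 0)
  # jittered train: recovered inter-event CV close to generator truth
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    taps <- cumsum(abs(rnorm(25, 0.4, 0.05)))
    x <- rep(0, length(t))
    for (tc in taps[taps < 9.8]) x <- x + exp(-((t - tc)^2) / (2 * 0.02^2))
    truth <- rhythmicVariation(taps[taps < 9.8])
    got <- rhythmicVariation(detectEvents(x, fs))
    ok <- ok + (abs(got - truth) / truth < 0.05)
  }
  expect_gte(ok, 9)
})

test_that("DTW equals exhaustive monotone-path enumeration", {
  expect_equal(dtwError(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtwError(c(0, 0, 1), c(0, 1)), 0)
  set.seed(42)
  for (i in 1:100) {
    a <- round(rnorm(sample(2:6, 1)), 2)
    b <- round(rnorm(sample(2:6, 1)), 2)
    expect_equal(dtwError(a, b), oracle_dtw(a, b), tolerance = 1e-12)
  }
  expect_error(dtwError(numeric(0), 1), "empty")
})

test_that("comprehensive delay recovers known lags", {
  fs <- 50
  set.seed(5)
  target <- rep(runif(10, -1, 1), each = fs)
  marker <- c(rep(target[1], 5), target[seq_len(length(target) - 5)])
  expect_equal(comprehensiveDelay(marker, target, fs), 0.1)
  expect_equal(comprehensiveDelay(target, target, fs), 0)
  expect_error(comprehensiveDelay(rep(1, 200), rep(1, 200), fs), "constant")
  # noisy delayed copy: within one sample of truth in almost all runs
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    tgt <- rep(runif(8, -1, 1), each = fs)
    d <- sample(3:12, 1)
    mk <- c(rep(tgt[1], d), tgt[seq_len(length(tgt) - d)])
    mk <- mk + sd(tgt) / sqrt(10) * rnorm(length(mk)) # 10 dB SNR
    hits <- hits + (abs(comprehensiveDelay(mk, tgt, fs) - d / fs) <= 1 / fs + 1e-9)
  }
  expect_gte(hits, 95)
})

test_that("Fitts index of performance follows its closed form", {
  expect_equal(indexOfPerformance(0.25, 0.5, 1), 0)
  expect_equal(indexOfPerformance(2, 0.5, 1), 3)
  expect_equal(indexOfPerformance(2, 0.5, 2),
               indexOfPerformance(2, 0.5, 1) / 2)
  expect_error(indexOfPerformance(-1, 0.5, 1), "positive")
})

test_that("directional changes count acceleration reversals", {
  expect_equal(directionalChanges(seq(0, 10, by = 0.1)), 0L)
  expect_equal(directionalChanges(rep(3, 50)), 0L)
  # sampled sinusoid: matches a direct sign-change counter
  t <- seq(0, 4, by = 0.01)
  for (f in c(1, 2, 3)) {
    x <- sin(2 * pi * f * t)
    s <- sign(diff(x, differences = 2))
    s <- s[s != 0]
    expect_equal(directionalChanges(x), sum(diff(s) != 0))
  }
})

test_that("speech features recover prosody of synthetic bursts", {
  fs <- 1000
  t <- seq(1 / fs, 4, by = 1 / fs)
  mkenv <- function(onsets, zeta = 0.05, om = 2 * pi * 40) {
    env <- rep(1e-4, length(t))
    for (on in onsets) {
      tau <- t - on
      u <- tau >= 0 & tau < 0.25
      env[u] <- env[u] + exp(-zeta * om * tau[u]) * pmax(sin(om * tau[u]), 0)
    }
    env
  }
  # identical equally spaced bursts: all regularities 0
  sf <- speechFeatures(mkenv(seq(0.3, 3.1, by = 0.4)), fs)
  expect_equal(sf$n_syllables, 8)
  expect_equal(sf$gap_reg, 0, tolerance = 1e-6)
  expect_equal(sf$duration_reg, 0, tolerance = 1e-6)
  expect_equal(sf$compensation_reg, 0, tolerance = 1e-6)
  # damping ratio via log decrement
  expect_equal(sf$damping_ratio, 0.05, tolerance = 0.005)
  # alternating gaps 0.3 / 0.5 s: gap regularity equals the hand SD
  ons <- cumsum(c(0.3, rep(c(0.3, 0.5), 4)))
  sf2 <- speechFeatures(mkenv(ons), fs)
  expect_equal(sf2$gap_reg, sd(diff(ons)), tolerance = 1e-3)
  expect_error(speechFeatures(rep(0, 4000), fs), "syllables")
})

test_that("sway entropy equals fuzzy entropy of the derived velocity", {
  set.seed(21)
  rec <- coaStar:::baseRomberg("x", "front", "open")
  se <- swayEntropy(list(rec), decimate = 1L)
  a <- signalChannels(rec)[, "acc_ml"]
  v <- cumsum(resid(lm(a ~ seq_along(a)))) / samplingRate(rec)
  expect_equal(unname(se["ROM_entropy_ML_front_open"]),
               fuzzyEntropy(v, m = 2, r = 0.2 * sd(v), n_exp = 2),
               tolerance = 1e-12)
  # zero-acceleration record: all entropies 0
  zero <- coaStar:::makeRecord("x", "ROM", 50,
    cbind(acc_ml = rep(0, 500), acc_ap = rep(0, 500), acc_vt = rep(0, 500)),
    c(sensor = "back", eyes = "closed")
  )
  sez <- swayEntropy(list(zero))
  expect_true(all(sez[grepl("back_closed", names(sez))] == 0))
  # conditions without a record stay missing
  expect_true(all(is.na(sez[grepl("front", names(sez))])))
})

test_that("feature extraction fills the taxonomy and flags missing tests", {
  cfg <- cohortConfig(n_controls = 2, n_ataxic = 2, seed = 5,
                      mode = "raw_signals")
  sim <- simulateCohort(cfg)
  recs <- sim$records[[1]]
  v <- extractSubjectFeatures(recs)
  expect_length(v, 172)
  expect_true(all(is.finite(v)))
  expect_length(attr(v, "missing_tests"), 0)
  # second run on identical input gives identical values
  expect_identical(as.numeric(v), as.numeric(extractSubjectFeatures(recs)))
  # dropping WAL leaves 45 missing values and a partial flag
  noWal <- Filter(function(r) r@test != "WAL", recs)
  v2 <- extractSubjectFeatures(noWal)
  expect_equal(sum(is.finite(v2)), 127)
  expect_equal(sum(is.na(v2)), 45)
  expect_equal(attr(v2, "missing_tests"), "WAL")
  expect_true(attr(v2, "partial"))
})
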