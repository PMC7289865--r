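#' Configuration of a synthetic assessment cohort
#'
#' Describes the cohort to simulate: group sizes, the severity range of
#' the ataxic group, per-domain affectedness probabilities, the relative
#' perturbation strength of the four STAR dimensions, and whether raw
#' per-test recordings or a ready-made feature table is produced.
#'
#' Defaults mirror the reference study conditions: 11 controls and 23
#' ataxic subjects, mild-to-severe impairment, gait affected in nearly
#' all patients and the remaining domains in well over half, and an even
#' STAR perturbation mix.
#'
#' @param n_controls,n_ataxic group sizes (each >= 2).
#' @param seed master seed; every subject draws from its own substream.
#' @param severity_range range of the per-subject severity in [0, 1].
#' @param domain_affect_prob probabilities that an ataxic subject is
#'   affected in speech, upper limb, lower limb, balance and gait; at
#'   least one domain is always affected.
#' @param star_mix nonnegative weights of the Stability, Timing, Accuracy
#'   and Rhythmicity perturbations; must sum to 1.
#' @param mode \code{"feature_table"} draws the 172-feature table
#'   directly (correlated within-test blocks, group effects scaled by
#'   severity and \code{star_mix}); \code{"raw_signals"} synthesises the
#'   per-test recordings to be run through the feature extractors.
#' @param effect_scale effect size (in within-group SD units) of a fully
#'   severe, fully weighted perturbation in feature-table mode.
#' @return validated configuration list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(n_controls = 11, n_ataxic = 23, seed = 1,
                         severity_range = c(0.3, 1),
                         domain_affect_prob = c(
                           speech = 0.6, upper_limb = 0.8, lower_limb = 0.7,
                           balance = 0.8, gait = 0.95
                         ),
                         star_mix = c(S = 0.25, T = 0.25, A = 0.25, R = 0.25),
                         mode = c("feature_table", "raw_signals"),
                         effect_scale = 6) {
  mode <- match.arg(mode)
  if (n_controls < 2 || n_ataxic < 2) {
    stop("configuration error: need at least 2 subjects per group")
  }
  if (length(domain_affect_prob) != 5 ||
      any(domain_affect_prob < 0 | domain_affect_prob > 1)) {
    stop("configuration error: domain_affect_prob must be 5 values in [0, 1]")
  }
  if (length(severity_range) != 2 ||
      any(severity_range < 0 | severity_range > 1) ||
      severity_range[1] > severity_range[2]) {
    stop("configuration error: severity_range must be an ordered pair in [0, 1]")
  }
  if (length(star_mix) != 4 || any(star_mix < 0) ||
      abs(sum(star_mix) - 1) > 1e-9) {
    stop("configuration error: star_mix must be 4 nonnegative weights summing to 1")
  }
  names(domain_affect_prob) <- DOMAIN_IDS
  names(star_mix) <- STAR_IDS
  structure(
    list(
      n_controls = as.integer(n_controls), n_ataxic = as.integer(n_ataxic),
      seed = as.integer(seed), severity_range = severity_range,
      domain_affect_prob = domain_affect_prob, star_mix = star_mix,
      mode = mode, effect_scale = effect_scale
    ),
    class = "CohortConfig"
  )
}

# SARA item catalogue: id, domain used for grouping, maximum score.
saraItemTable <- function() {
  data.frame(
    item = c(
      "sara1_gait", "sara2_stance", "sara3_sitting", "sara4_speech",
      "sara5_finger_L", "sara5_finger_R", "sara6_nosefinger_L",
      "sara6_nosefinger_R", "sara7_hand_L", "sara7_hand_R",
      "sara8_heelshin_L", "sara8_heelshin_R"
    ),
    domain = c(
      "gait", "balance", "balance", "speech",
      "upper_limb", "upper_limb", "upper_limb", "upper_limb",
      "upper_limb", "upper_limb", "lower_limb", "lower_limb"
    ),
    max = c(8, 6, 4, 6, 4, 4, 4, 4, 4, 4, 4, 4),
    stringsAsFactors = FALSE
  )
}

# Draw one subject's ground truth under its own RNG substream.
drawSubjectTruth <- function(config, k, group) {
  withSubSeed(config$seed, k, {
    sara <- saraItemTable()
    scores <- stats::setNames(rep(0, nrow(sara)), sara$item)
    if (group == "control") {
      severity <- 0
      domains <- stats::setNames(rep(0L, 5), DOMAIN_IDS)
    } else {
      severity <- stats::runif(1, config$severity_range[1],
                               config$severity_range[2])
      repeat {
        domains <- stats::setNames(
          stats::rbinom(5, 1, config$domain_affect_prob), DOMAIN_IDS
        )
        if (sum(domains) >= 1) break
      }
      for (j in seq_len(nrow(sara))) {
        if (domains[[sara$domain[j]]] == 1) {
          # item score: severity binned onto the item's printed range
          # (an affected domain always scores at least 1)
          scores[j] <- max(1, min(
            sara$max[j],
            round(severity * sara$max[j] * stats::runif(1, 0.5, 1))
          ))
        }
      }
    }
    c(
      list(group = group, severity = severity),
      as.list(domains), as.list(scores)
    )
  })
}

#' Simulate a synthetic assessment cohort
#'
#' Generates ground-truth subject records (group, severity, per-domain
#' affectedness, SARA item scores) and either raw per-test recordings or
#' a ready-made 172-feature table, deterministically for a fixed seed.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with elements \code{truth} (data.frame keyed by
#'   \code{subject_id}), \code{features} (a \linkS4class{CoaFeatureSet},
#'   feature-table mode only), \code{records} (named list of
#'   \linkS4class{SignalRecord} lists per subject, raw mode only) and
#'   \code{config}.
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "CohortConfig")) {
    stop("configuration error: not a CohortConfig")
  }
  n <- config$n_controls + config$n_ataxic
  ids <- sprintf("S%03d", seq_len(n))
  groups <- c(
    rep("control", config$n_controls),
    rep("ataxic", config$n_ataxic)
  )
  truth <- do.call(rbind, lapply(seq_len(n), function(k) {
    as.data.frame(
      c(list(subject_id = ids[k]), drawSubjectTruth(config, k, groups[k])),
      stringsAsFactors = FALSE
    )
  }))
  rownames(truth) <- truth$subject_id

  if (config$mode == "feature_table") {
    feats <- simulateFeatureTable(config, truth)
    list(truth = truth, features = feats, records = NULL, config = config)
  } else {
    records <- lapply(seq_len(n), function(k) {
      makeSubjectRecords(config, truth[k, ], k)
    })
    names(records) <- ids
    list(truth = truth, features = NULL, records = records, config = config)
  }
}

# Direction in which impairment moves a feature: entropies, variabilities,
# errors, delays and magnitudes rise; resonant frequencies and the Fitts
# index of performance fall (slower, less efficient movement).
featureEffectDirection <- function(meta) {
  ifelse(grepl("_RF_|_iop_|^SPE_RF$", meta$feature_id), -1, 1)
}

# Feature-table mode: correlated within-test blocks plus group effects
# scaled by severity and the STAR mix.
simulateFeatureTable <- function(config, truth) {
  meta <- featureTaxonomy()
  n <- nrow(truth)
  p <- nrow(meta)
  dirs <- featureEffectDirection(meta)
  rho <- 0.5 # within-test feature correlation
  M <- matrix(NA_real_, nrow = p, ncol = n,
              dimnames = list(meta$feature_id, truth$subject_id))
  for (k in seq_len(n)) {
    M[, k] <- withSubSeed(config$seed, 10000 + k, {
      u <- stats::setNames(stats::rnorm(length(TEST_IDS)), TEST_IDS)
      eps <- stats::rnorm(p)
      base <- sqrt(rho) * u[meta$test] + sqrt(1 - rho) * eps
      shift <- 0
      if (truth$group[k] == "ataxic") {
        affected <- unlist(truth[k, DOMAIN_IDS]) == 1
        shift <- config$effect_scale * truth$severity[k] *
          config$star_mix[meta$star] * dirs *
          as.numeric(affected[meta$domain])
      }
      base + shift
    })
  }
  newCoaFeatureSet(M, meta, truth)
}

#' Construct a CoaFeatureSet from a feature matrix
#'
#' @param M features x subjects numeric matrix, rows named by taxonomy
#'   feature ids.
#' @param meta feature taxonomy (default the shipped
#'   \code{\link{featureTaxonomy}}).
#' @param truth subject truth table (one row per subject).
#' @return a \linkS4class{CoaFeatureSet}.
#' @export
coaFeatureSet <- function(M, meta = featureTaxonomy(), truth) {
  meta <- meta[match(rownames(M), meta$feature_id), ]
  if (anyNA(meta$feature_id)) stop("unknown feature ids in matrix rows")
  newCoaFeatureSet(M, meta, truth)
}

# Construct the CoaFeatureSet container.
newCoaFeatureSet <- function(M, meta, truth) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = M),
    rowData = S4Vectors::DataFrame(meta, row.names = meta$feature_id),
    colData = S4Vectors::DataFrame(truth, row.names = truth$subject_id)
  )
  methods::new("CoaFeatureSet", se)
}

# ---- raw signal synthesis -------------------------------------------------

# Per-subject base kinematic parameters (individual variation).
drawSubjectParams <- function() {
  list(
    f0 = c(DDK = 2.5, FNT = 1.0, FIN = 2.2, FOO = 1.8, HST = 0.9) *
      stats::runif(5, 0.9, 1.1),
    amp = stats::runif(1, 0.8, 1.2),
    stride = stats::runif(1, 0.9, 1.1),
    syl_rate = stats::runif(1, 3.6, 4.4),
    zeta = stats::runif(1, 0.045, 0.06)
  )
}

makeRecord <- function(subject, test, fs, channels, condition = character(0)) {
  methods::new("SignalRecord",
    subject = subject, test = test, fs = fs,
    channels = channels, condition = condition
  )
}

# Base recording of a repetitive limb test (sinusoidal primary axis or
# tap-pulse train, pink-noise secondary axes).
baseRepetitive <- function(subject, test, side, p, fs = 50, dur = 12) {
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  f0 <- p$f0[[test]]
  A <- p$amp
  if (test %in% c("FIN", "FOO")) {
    # tap-pulse train with small natural jitter
    iv0 <- 1 / f0
    taps <- cumsum(stats::rnorm(ceiling(dur / iv0) + 2, iv0, 0.04 * iv0))
    taps <- taps[taps > 0.2 & taps < dur - 0.2]
    prim <- rep(0, n)
    for (tp in taps) {
      prim <- prim + A * exp(-((t - tp)^2) / (2 * 0.04^2))
    }
    prim <- prim + 0.05 * A * pinkNoise(n)
  } else {
    prim <- A * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi)) +
      0.15 * A * pinkNoise(n)
  }
  gyro_y <- 0.8 * A * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi)) +
    0.1 * A * pinkNoise(n)
  ch <- cbind(
    acc_x = 0.25 * A * pinkNoise(n),
    acc_y = prim,
    acc_z = 0.25 * A * pinkNoise(n),
    gyro_x = 0.2 * A * pinkNoise(n),
    gyro_y = gyro_y,
    gyro_z = 0.2 * A * pinkNoise(n)
  )
  makeRecord(subject, test, fs, ch, c(side = side))
}

baseBallistic <- function(subject, side, fs = 50, dur = 12) {
  n <- round(dur * fs)
  step <- round(2 * fs)
  nstep <- ceiling(n / step)
  mk <- function() {
    tgt <- rep(stats::runif(nstep, -1, 1), each = step)[seq_len(n)]
    # first-order pursuit with a physiological lag
    lag <- round(0.15 * fs)
    alpha <- 1 - exp(-1 / (0.12 * fs))
    m <- numeric(n)
    for (i in 2:n) {
      ti <- if (i > lag) tgt[i - lag] else tgt[1]
      m[i] <- m[i - 1] + alpha * (ti - m[i - 1])
    }
    list(target = tgt, marker = m + 0.02 * pinkNoise(n))
  }
  h <- mk()
  v <- mk()
  ch <- cbind(
    marker_h = h$marker, marker_v = v$marker,
    target_h = h$target, target_v = v$target
  )
  makeRecord(subject, "BAL", fs, ch, c(side = side))
}

baseRomberg <- function(subject, sensor, eyes, fs = 50, dur = 28) {
  n <- round(dur * fs)
  amp <- 0.05 * if (eyes == "closed") 1.3 else 1
  ch <- cbind(
    acc_ml = amp * pinkNoise(n),
    acc_ap = amp * pinkNoise(n),
    acc_vt = 0.7 * amp * pinkNoise(n)
  )
  makeRecord(subject, "ROM", fs, ch, c(sensor = sensor, eyes = eyes))
}

baseWalking <- function(subject, speed, p, fs = 50, dur = 60) {
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  fstride <- p$stride *
    c(slow = 0.75, preferred = 0.95, fast = 1.15)[[speed]]
  fstep <- 2 * fstride
  harm <- function(f, a, ph = stats::runif(1, 0, 2 * pi)) {
    a * (sin(2 * pi * f * t + ph) + 0.3 * sin(4 * pi * f * t + 2 * ph))
  }
  ankle <- function(phase) {
    cbind(
      ml = harm(fstride, 0.25) + 0.05 * pinkNoise(n),
      ap = harm(fstride, 0.45, phase) + 0.05 * pinkNoise(n),
      vt = harm(fstride, 0.6, phase) + 0.05 * pinkNoise(n)
    )
  }
  aL <- ankle(0)
  aR <- ankle(pi)
  ch <- cbind(
    trunk_ml = harm(fstride, 0.2) + 0.04 * pinkNoise(n),
    trunk_ap = harm(fstep, 0.25) + 0.04 * pinkNoise(n),
    trunk_vt = harm(fstep, 0.35) + 0.04 * pinkNoise(n),
    ankle_L_ml = aL[, 1], ankle_L_ap = aL[, 2], ankle_L_vt = aL[, 3],
    ankle_R_ml = aR[, 1], ankle_R_ap = aR[, 2], ankle_R_vt = aR[, 3]
  )
  makeRecord(subject, "WAL", fs, ch, c(speed = speed))
}

baseSpeech <- function(subject, p, fs = 1000, dur = 4.5) {
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  gap0 <- 1 / p$syl_rate
  onsets <- cumsum(stats::rnorm(ceiling(dur / gap0) + 2, gap0, 0.02 * gap0))
  onsets <- onsets[onsets > 0.15 & onsets < dur - 0.3]
  fr <- 40 # ripple (articulation resonance) frequency, Hz
  env <- rep(0, n)
  for (on in onsets) {
    tau <- t - on
    use <- tau >= 0 & tau < 0.22
    amp <- stats::runif(1, 0.9, 1.1)
    # decaying ripple: exponential decay at damping zeta carrying an
    # oscillation at fr; strictly positive between ripple crests
    env[use] <- env[use] + amp * exp(-p$zeta * 2 * pi * fr * tau[use]) *
      (0.55 + 0.45 * cos(2 * pi * fr * tau[use]))
  }
  env <- env + 0.01 * abs(stats::rnorm(n))
  makeRecord(subject, "SPE", fs, cbind(audio_envelope = env), character(0))
}

# All records of one subject; the subject's substream makes generation
# reproducible and fold-stable.
makeSubjectRecords <- function(config, truthRow, k) {
  withSubSeed(config$seed, 20000 + k, {
    p <- drawSubjectParams()
    sev <- truthRow$severity
    mix <- config$star_mix
    affected <- unlist(truthRow[DOMAIN_IDS]) == 1
    sevFor <- function(domain) if (affected[[domain]]) sev else 0
    recs <- list()
    for (test in c("DDK", "FNT", "FIN", "BAL")) {
      for (side in c("L", "R")) {
        base <- if (test == "BAL") {
          baseBallistic(truthRow$subject_id, side)
        } else {
          baseRepetitive(truthRow$subject_id, test, side, p)
        }
        recs[[length(recs) + 1L]] <-
          perturbSignal(base, sevFor("upper_limb"), mix)
      }
    }
    for (test in c("FOO", "HST")) {
      for (side in c("L", "R")) {
        base <- baseRepetitive(truthRow$subject_id, test, side, p)
        recs[[length(recs) + 1L]] <-
          perturbSignal(base, sevFor("lower_limb"), mix)
      }
    }
    for (sensor in c("front", "back")) {
      for (eyes in c("open", "closed")) {
        base <- baseRomberg(truthRow$subject_id, sensor, eyes)
        recs[[length(recs) + 1L]] <-
          perturbSignal(base, sevFor("balance"), mix)
      }
    }
    for (speed in c("slow", "preferred", "fast")) {
      base <- baseWalking(truthRow$subject_id, speed, p)
      recs[[length(recs) + 1L]] <- perturbSignal(base, sevFor("gait"), mix)
    }
    recs[[length(recs) + 1L]] <-
      perturbSignal(baseSpeech(truthRow$subject_id, p), sevFor("speech"), mix)
    recs
  })
}

#' Apply a severity-scaled STAR perturbation to a recording
#'
#' Degrades a base recording along the four Holmesian dimensions in
#' proportion to \code{severity} times the corresponding \code{star_mix}
#' weight: Stability raises secondary-axis power, Timing adds onset
#' latency and slows the primary movement, Accuracy adds low-frequency
#' deviation from the efficient path, and Rhythmicity inflates
#' inter-event-interval variability and amplitude jitter. A severity of 0
#' returns the base recording unchanged.
#'
#' @param base a \linkS4class{SignalRecord}.
#' @param severity impairment severity in [0, 1].
#' @param star_mix 4 nonnegative STAR weights.
#' @return the perturbed \linkS4class{SignalRecord}.
#' @export
perturbSignal <- function(base, severity, star_mix) {
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (!(base@test %in% TEST_IDS)) stop("unknown test id")
  if (severity == 0) return(base)
  s <- severity * star_mix
  names(s) <- STAR_IDS
  fs <- base@fs
  ch <- base@channels
  n <- nrow(ch)
  t <- seq_len(n) / fs

  warpChannels <- function(ch, rate_sd, smooth) {
    rate <- pmax(0.3, 1 + rate_sd * driftNoise(n, smooth))
    at <- 1 + cumsum(rate) - rate[1]
    resampleChannels(ch, at)
  }
  delaySlow <- function(ch, latency, slow) {
    at <- 1 + (seq_len(n) - 1 - latency * fs) / (1 + slow)
    resampleChannels(ch, at)
  }

  if (base@test %in% c("DDK", "FNT", "FIN", "FOO", "HST")) {
    if (s[["T"]] > 0) ch <- delaySlow(ch, 0.8 * s[["T"]], 0.35 * s[["T"]])
    if (s[["R"]] > 0) {
      ch <- warpChannels(ch, 0.45 * s[["R"]], round(fs / 2))
      ch <- ch * (1 + 0.3 * s[["R"]] * driftNoise(n, round(fs / 2)))
    }
    if (s[["S"]] > 0) {
      aA <- 0.9 * s[["S"]] * stats::sd(ch[, "acc_y"])
      aG <- 0.9 * s[["S"]] * stats::sd(ch[, "gyro_y"])
      f2 <- stats::runif(1, 1.5, 3.5)
      for (cn in c("acc_x", "acc_z")) {
        ch[, cn] <- ch[, cn] + aA * (0.6 * pinkNoise(n) +
          0.6 * sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi)))
      }
      for (cn in c("gyro_x", "gyro_z")) {
        ch[, cn] <- ch[, cn] + aG * (0.6 * pinkNoise(n) +
          0.6 * sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi)))
      }
    }
    if (s[["A"]] > 0) {
      ch[, "acc_y"] <- ch[, "acc_y"] +
        0.5 * s[["A"]] * stats::sd(ch[, "acc_y"]) * driftNoise(n)
    }
  } else if (base@test == "BAL") {
    mcols <- c("marker_h", "marker_v")
    if (s[["T"]] > 0) {
      at <- seq_len(n) - 0.35 * s[["T"]] * fs
      ch[, mcols] <- resampleChannels(ch[, mcols, drop = FALSE], at)
    }
    if (s[["A"]] > 0) {
      for (cn in mcols) {
        ch[, cn] <- ch[, cn] + 0.35 * s[["A"]] * driftNoise(n) +
          0.15 * s[["A"]] * sample(c(-1, 1), 1)
      }
    }
    if (s[["S"]] > 0) {
      for (cn in mcols) ch[, cn] <- ch[, cn] + 0.15 * s[["S"]] * pinkNoise(n)
    }
    if (s[["R"]] > 0) {
      for (cn in mcols) {
        ch[, cn] <- ch[, cn] * (1 + 0.25 * s[["R"]] * driftNoise(n))
      }
    }
  } else if (base@test == "ROM") {
    ef <- if (base@condition[["eyes"]] == "closed") 1.6 else 1
    if (s[["S"]] > 0) {
      ch[, "acc_ml"] <- ch[, "acc_ml"] + 0.12 * s[["S"]] * ef * stats::rnorm(n)
      ch[, "acc_ap"] <- ch[, "acc_ap"] + 0.12 * s[["S"]] * ef * stats::rnorm(n)
    }
    if (s[["A"]] > 0) {
      ch[, "acc_vt"] <- ch[, "acc_vt"] + 0.12 * s[["A"]] * ef * stats::rnorm(n)
    }
    if (s[["T"]] > 0) ch <- ch + 0.05 * s[["T"]] * ef * driftNoise(n)
    if (s[["R"]] > 0) ch <- ch * (1 + 0.3 * s[["R"]] * driftNoise(n))
  } else if (base@test == "WAL") {
    if (s[["T"]] > 0) ch <- delaySlow(ch, 0.5 * s[["T"]], 0.25 * s[["T"]])
    if (s[["R"]] > 0) {
      ch <- warpChannels(ch, 0.35 * s[["R"]], round(fs))
      ch[, "trunk_ap"] <- ch[, "trunk_ap"] + 0.25 * s[["R"]] * stats::rnorm(n)
      for (cn in c("ankle_L_ap", "ankle_R_ap")) {
        ch[, cn] <- ch[, cn] + 0.3 * s[["R"]] * pinkNoise(n)
      }
    }
    if (s[["S"]] > 0) {
      ch[, "trunk_vt"] <- ch[, "trunk_vt"] + 0.25 * s[["S"]] * stats::rnorm(n)
      for (cn in c("ankle_L_vt", "ankle_R_vt")) {
        ch[, cn] <- ch[, cn] + 0.3 * s[["S"]] * pinkNoise(n)
      }
    }
    if (s[["A"]] > 0) {
      ch[, "trunk_ml"] <- ch[, "trunk_ml"] +
        0.25 * s[["A"]] * stats::rnorm(n) + 0.2 * s[["A"]] * driftNoise(n)
      for (cn in c("ankle_L_ml", "ankle_R_ml")) {
        ch[, cn] <- ch[, cn] + 0.3 * s[["A"]] * pinkNoise(n)
      }
    }
  } else if (base@test == "SPE") {
    env <- ch[, "audio_envelope"]
    if (s[["T"]] > 0) {
      at <- 1 + (seq_len(n) - 1 - 0.3 * s[["T"]] * fs) / (1 + 0.25 * s[["T"]])
      env <- stats::approx(seq_len(n), env, xout = pmin(pmax(at, 1), n))$y
    }
    if (s[["R"]] > 0) {
      rate <- pmax(0.3, 1 + 0.3 * s[["R"]] * driftNoise(n, round(0.3 * fs)))
      at <- 1 + cumsum(rate) - rate[1]
      env <- stats::approx(seq_len(n), env,
                           xout = pmin(pmax(at, 1), n))$y
      env <- env * (1 + 0.35 * s[["R"]] * driftNoise(n, round(0.3 * fs)))
    }
    if (s[["S"]] > 0) {
      # compress the decay: peaks fall off more slowly, i.e. the
      # articulatory oscillation is less damped
      mx <- max(env)
      env <- mx * (pmax(env, 0) / mx)^(1 - 0.45 * s[["S"]])
    }
    if (s[["A"]] > 0) {
      env <- env + 0.15 * s[["A"]] * abs(driftNoise(n, round(0.2 * fs)))
    }
    ch[, "audio_envelope"] <- pmax(env, 0)
  }
  makeRecord(base@subject, base@test, fs, ch, base@condition)
}
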