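# Per-test feature extraction: maps SignalRecords onto the 172-feature
# taxonomy.

# remove a moving-average trend (window in seconds)
highpassDetrend <- function(x, fs, window = 2) {
  k <- max(3L, round(window * fs))
  if (k %% 2 == 0) k <- k + 1L
  tr <- stats::filter(x, rep(1 / k, k), sides = 2)
  tr[is.na(tr)] <- mean(x)
  as.numeric(x - tr)
}

# orientation angle from gyroscope: high-pass detrended then integrated
gyroAngle <- function(gyro, fs) cumsum(highpassDetrend(gyro, fs)) / fs

# angular acceleration from gyroscope: first difference scaled by fs
gyroAngAcc <- function(gyro, fs) c(0, diff(gyro)) * fs

rfmr <- function(x, fs) {
  r <- resonanceProfile(x, fs)
  c(rf = r$rf, mr = r$mr)
}

extractRepetitive <- function(rec, out) {
  fs <- rec@fs
  ch <- rec@channels
  side <- rec@condition[["side"]]
  test <- rec@test
  if (test == "DDK") {
    for (ax in c("X", "Y", "Z")) {
      cn <- paste0("gyro_", tolower(ax))
      r <- rfmr(gyroAngle(ch[, cn], fs), fs)
      out[sprintf("DDK_RF_angle_%s_%s", ax, side)] <- r["rf"]
      out[sprintf("DDK_MR_angle_%s_%s", ax, side)] <- r["mr"]
    }
    for (ax in c("X", "Z")) {
      r <- rfmr(ch[, paste0("acc_", tolower(ax))], fs)
      out[sprintf("DDK_RF_acc_%s_%s", ax, side)] <- r["rf"]
      out[sprintf("DDK_MR_acc_%s_%s", ax, side)] <- r["mr"]
    }
  } else if (test == "FNT") {
    for (ax in c("X", "Y", "Z")) {
      r <- rfmr(gyroAngAcc(ch[, paste0("gyro_", tolower(ax))], fs), fs)
      out[sprintf("FNT_RF_angacc_%s_%s", ax, side)] <- r["rf"]
      out[sprintf("FNT_MR_angacc_%s_%s", ax, side)] <- r["mr"]
    }
    # only X/Z and Y rows of the angular block are catalogued; acc adds
    # RF on all three axes and MR on X
    for (ax in c("X", "Y", "Z")) {
      r <- rfmr(ch[, paste0("acc_", tolower(ax))], fs)
      out[sprintf("FNT_RF_acc_%s_%s", ax, side)] <- r["rf"]
      if (ax == "X") out[sprintf("FNT_MR_acc_X_%s", side)] <- r["mr"]
    }
  } else if (test %in% c("FIN", "FOO")) {
    chans <- if (test == "FIN") {
      c(acc_x = "acc_X", acc_z = "acc_Z", gyro_x = "gyro_X")
    } else {
      c(gyro_y = "gyro_Y", gyro_z = "gyro_Z")
    }
    for (cn in names(chans)) {
      mse <- multiscaleEntropy(ch[, cn], scales = 1:3)
      parts <- strsplit(chans[[cn]], "_")[[1]]
      for (sc in 1:3) {
        out[sprintf("%s_MSE%d_%s_%s_%s", test, sc, parts[1], parts[2], side)] <-
          mse[sc]
      }
    }
    ev <- detectEvents(ch[, "acc_y"], fs, min_separation = 0.15)
    out[sprintf("%s_RV_%s", test, side)] <-
      if (length(ev) >= 3) rhythmicVariation(ev) else NA_real_
  } else if (test == "HST") {
    for (ax in c("X", "Y", "Z")) {
      r <- rfmr(ch[, paste0("acc_", tolower(ax))], fs)
      out[sprintf("HST_RF_acc_%s_%s", ax, side)] <- r["rf"]
      if (ax %in% c("X", "Z") ||
          sprintf("HST_MR_acc_%s_%s", ax, side) %in% names(out)) {
        out[sprintf("HST_MR_acc_%s_%s", ax, side)] <- r["mr"]
      }
      ra <- rfmr(gyroAngle(ch[, paste0("gyro_", tolower(ax))], fs), fs)
      id_rf <- sprintf("HST_RF_angle_%s_%s", ax, side)
      if (id_rf %in% names(out)) out[id_rf] <- ra["rf"]
      id_mr <- sprintf("HST_MR_angle_%s_%s", ax, side)
      if (id_mr %in% names(out)) out[id_mr] <- ra["mr"]
    }
  }
  out
}

extractBallistic <- function(rec, out, target_width = 0.1) {
  fs <- rec@fs
  ch <- rec@channels
  side <- rec@condition[["side"]]
  for (ax in c("H", "V")) {
    m <- ch[, paste0("marker_", tolower(ax))]
    tg <- ch[, paste0("target_", tolower(ax))]
    out[sprintf("BAL_dirchange_%s_%s", ax, side)] <- directionalChanges(m)
    out[sprintf("BAL_delay_%s_%s", ax, side)] <-
      comprehensiveDelay(m, tg, fs)
    out[sprintf("BAL_dtw_%s_%s", ax, side)] <- dtwError(m, tg)
  }
  # Fitts-law index of performance per target jump
  tg2 <- ch[, c("target_h", "target_v")]
  jumps <- which(rowSums(abs(diff(tg2))) > 1e-9) + 1L
  mk2 <- ch[, c("marker_h", "marker_v")]
  iops <- c()
  bounds <- c(jumps, nrow(ch) + 1L)
  for (j in seq_along(jumps)) {
    i0 <- jumps[j]
    i1 <- bounds[j + 1L] - 1L
    D <- sqrt(sum((tg2[i0, ] - tg2[i0 - 1L, ])^2))
    D <- max(D, target_width / 2)
    derr <- sqrt(rowSums((mk2[i0:i1, , drop = FALSE] -
      matrix(tg2[i0, ], i1 - i0 + 1, 2, byrow = TRUE))^2))
    hit <- which(derr < target_width)
    MT <- (if (length(hit)) hit[1] else (i1 - i0 + 1)) / fs
    iops <- c(iops, indexOfPerformance(D, target_width, MT))
  }
  out[sprintf("BAL_iop_%s", side)] <- mean(iops)
  out
}

extractWalking <- function(rec, out, decimate = 2L) {
  fs <- rec@fs
  ch <- rec@channels
  speed <- rec@condition[["speed"]]
  axmap <- c(ML = "ml", AP = "ap", VT = "vt")
  for (ax in names(axmap)) {
    a <- ch[, paste0("trunk_", axmap[[ax]])]
    vel <- cumsum(highpassDetrend(a, fs, window = 4)) / fs
    vel <- vel[seq(1, length(vel), by = decimate)] # entropy on ~25 Hz series
    s <- stats::sd(vel)
    out[sprintf("WAL_fuzzyen_vel_%s_%s", ax, speed)] <-
      if (s == 0) 0 else fuzzyEntropy(vel, m = 2, r = 0.2 * s, n_exp = 2)
    for (side in c("L", "R")) {
      r <- rfmr(ch[, sprintf("ankle_%s_%s", side, axmap[[ax]])], fs)
      out[sprintf("WAL_RF_%s_%s_%s", ax, side, speed)] <- r["rf"]
      out[sprintf("WAL_MR_%s_%s_%s", ax, side, speed)] <- r["mr"]
    }
  }
  out
}

extractSpeech <- function(rec, out) {
  sf <- try(speechFeatures(rec@channels[, "audio_envelope"], rec@fs),
            silent = TRUE)
  if (inherits(sf, "try-error")) return(out)
  out["SPE_damping_ratio"] <- sf$damping_ratio
  out["SPE_RF"] <- sf$rf
  out["SPE_compensation_reg"] <- sf$compensation_reg
  out["SPE_peak_prominence"] <- sf$peak_prominence
  out["SPE_gap_reg"] <- sf$gap_reg
  out["SPE_duration_reg"] <- sf$duration_reg
  out
}

#' Extract the 172-feature vector of one subject
#'
#' Runs every per-test feature operator over a subject's recordings and
#' fills the taxonomy-ordered feature vector. Features of tests without a
#' recording stay NA and the missing tests are reported in the
#' \code{"missing_tests"} attribute; the vector is additionally flagged
#' \code{"partial"}.
#'
#' @param records list of \linkS4class{SignalRecord}s of one subject.
#' @return named numeric vector over the 172 taxonomy features, with
#'   attributes \code{missing_tests} and \code{partial}.
#' @export
extractSubjectFeatures <- function(records) {
  meta <- featureTaxonomy()
  out <- stats::setNames(rep(NA_real_, nrow(meta)), meta$feature_id)
  seen <- character(0)
  romRecords <- list()
  for (rec in records) {
    seen <- union(seen, rec@test)
    out <- switch(rec@test,
      DDK = , FNT = , FIN = , FOO = , HST = extractRepetitive(rec, out),
      BAL = extractBallistic(rec, out),
      WAL = extractWalking(rec, out),
      SPE = extractSpeech(rec, out),
      ROM = {
        romRecords[[length(romRecords) + 1L]] <- rec
        out
      }
    )
  }
  if (length(romRecords)) {
    se <- swayEntropy(romRecords)
    out[names(se)] <- se
  }
  missing <- setdiff(TEST_IDS, seen)
  attr(out, "missing_tests") <- missing
  attr(out, "partial") <- length(missing) > 0
  out
}

#' Extract features for a whole simulated cohort
#'
#' @param sim the result of \code{\link{simulateCohort}} in raw-signal
#'   mode (or a named list of per-subject record lists plus a truth
#'   table).
#' @param truth subject truth table; taken from \code{sim} when omitted.
#' @return a \linkS4class{CoaFeatureSet}.
#' @export
extractAllFeatures <- function(sim, truth = NULL) {
  records <- if (!is.null(sim$records)) sim$records else sim
  if (is.null(truth)) truth <- sim$truth
  meta <- featureTaxonomy()
  M <- vapply(records, function(recs) {
    v <- extractSubjectFeatures(recs)
    as.numeric(v)
  }, numeric(nrow(meta)))
  rownames(M) <- meta$feature_id
  colnames(M) <- names(records)
  newCoaFeatureSet(M, meta, truth[colnames(M), , drop = FALSE])
}
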