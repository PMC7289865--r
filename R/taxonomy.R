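#' The 172-feature taxonomy of the nine instrumented tests
#'
#' Enumerates every extracted feature together with its test, clinical
#' domain, STAR dimension tag (Stability, Timing, Accuracy, Rhythmicity),
#' and where applicable the sensor axis, body side, recording condition
#' and multiscale-entropy scale. Per-test counts are DDK 20, FNT 20,
#' FIN 20, BAL 14, FOO 14, HST 19, ROM 14, WAL 45 and SPE 6, summing
#' to 172.
#'
#' Axis conventions: inertial tests use the device X/Y/Z frame with Y the
#' primary movement axis; the trunk and ankle sensors in gait and stance
#' map X/Y/Z onto medio-lateral (ML), antero-posterior (AP) and vertical
#' (VT); camera tracking uses screen horizontal (H) and vertical (V).
#'
#' @return data.frame with columns \code{feature_id}, \code{test},
#'   \code{domain}, \code{star}, \code{axis}, \code{side},
#'   \code{condition}, \code{scale}.
#' @export
featureTaxonomy <- function() {
  rows <- list()
  add <- function(id, test, domain, star, axis = NA, side = NA,
                  condition = NA, scale = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = id, test = test, domain = domain, star = star,
      axis = as.character(axis), side = as.character(side),
      condition = as.character(condition), scale = as.integer(scale),
      stringsAsFactors = FALSE
    )
  }
  sides <- c("L", "R")

  # DDK (20, upper limb): spectral resonance of wrist angle and acceleration
  # during alternating pronation/supination. Y is the rotation axis.
  for (s in sides) {
    for (ax in c("X", "Z")) {
      add(sprintf("DDK_RF_angle_%s_%s", ax, s), "DDK", "upper_limb", "S", ax, s)
      add(sprintf("DDK_MR_angle_%s_%s", ax, s), "DDK", "upper_limb", "S", ax, s)
      add(sprintf("DDK_RF_acc_%s_%s", ax, s), "DDK", "upper_limb", "S", ax, s)
      add(sprintf("DDK_MR_acc_%s_%s", ax, s), "DDK", "upper_limb", "S", ax, s)
    }
    add(sprintf("DDK_RF_angle_Y_%s", s), "DDK", "upper_limb", "T", "Y", s)
    add(sprintf("DDK_MR_angle_Y_%s", s), "DDK", "upper_limb", "R", "Y", s)
  }

  # FNT (20, upper limb): resonance of angular acceleration and
  # acceleration during finger-nose pointing.
  for (s in sides) {
    for (ax in c("X", "Z")) {
      add(sprintf("FNT_RF_angacc_%s_%s", ax, s), "FNT", "upper_limb", "S", ax, s)
      add(sprintf("FNT_MR_angacc_%s_%s", ax, s), "FNT", "upper_limb", "S", ax, s)
    }
    add(sprintf("FNT_RF_angacc_Y_%s", s), "FNT", "upper_limb", "T", "Y", s)
    add(sprintf("FNT_MR_angacc_Y_%s", s), "FNT", "upper_limb", "R", "Y", s)
    for (ax in c("X", "Y", "Z")) {
      add(sprintf("FNT_RF_acc_%s_%s", ax, s), "FNT", "upper_limb", "S", ax, s)
    }
    add(sprintf("FNT_MR_acc_X_%s", s), "FNT", "upper_limb", "S", "X", s)
  }

  # FIN (20, upper limb): multiscale entropy (scales 1-3) of finger-tap
  # acceleration/gyro plus inter-tap rhythmic variation.
  for (s in sides) {
    for (sc in 1:3) {
      add(sprintf("FIN_MSE%d_acc_X_%s", sc, s), "FIN", "upper_limb", "S",
          "X", s, scale = sc)
      add(sprintf("FIN_MSE%d_acc_Z_%s", sc, s), "FIN", "upper_limb", "R",
          "Z", s, scale = sc)
      add(sprintf("FIN_MSE%d_gyro_X_%s", sc, s), "FIN", "upper_limb", "R",
          "X", s, scale = sc)
    }
    add(sprintf("FIN_RV_%s", s), "FIN", "upper_limb", "R", NA, s)
  }

  # BAL (14, upper limb): camera-tracked ballistic target chasing.
  for (s in sides) {
    for (ax in c("H", "V")) {
      add(sprintf("BAL_dirchange_%s_%s", ax, s), "BAL", "upper_limb", "S", ax, s)
      add(sprintf("BAL_delay_%s_%s", ax, s), "BAL", "upper_limb", "T", ax, s)
      add(sprintf("BAL_dtw_%s_%s", ax, s), "BAL", "upper_limb", "A", ax, s)
    }
    add(sprintf("BAL_iop_%s", s), "BAL", "upper_limb", "T", NA, s)
  }

  # FOO (14, lower limb): foot-tap entropy and rhythm.
  for (s in sides) {
    for (sc in 1:3) {
      add(sprintf("FOO_MSE%d_gyro_Y_%s", sc, s), "FOO", "lower_limb", "S",
          "Y", s, scale = sc)
      add(sprintf("FOO_MSE%d_gyro_Z_%s", sc, s), "FOO", "lower_limb", "S",
          "Z", s, scale = sc)
    }
    add(sprintf("FOO_RV_%s", s), "FOO", "lower_limb", "R", NA, s)
  }

  # HST (19, lower limb): heel-shin resonance; the single-sided
  # MR-of-angle-Y feature keeps the odd count.
  for (s in sides) {
    for (ax in c("X", "Z")) {
      add(sprintf("HST_RF_acc_%s_%s", ax, s), "HST", "lower_limb", "S", ax, s)
      add(sprintf("HST_MR_acc_%s_%s", ax, s), "HST", "lower_limb", "S", ax, s)
      add(sprintf("HST_RF_angle_%s_%s", ax, s), "HST", "lower_limb", "S", ax, s)
    }
    add(sprintf("HST_RF_acc_Y_%s", s), "HST", "lower_limb", "T", "Y", s)
    add(sprintf("HST_MR_acc_Y_%s", s), "HST", "lower_limb", "R", "Y", s)
    add(sprintf("HST_RF_angle_Y_%s", s), "HST", "lower_limb", "T", "Y", s)
  }
  add("HST_MR_angle_Y_L", "HST", "lower_limb", "S", "Y", "L")

  # ROM (14, balance): fuzzy entropy of postural sway velocity for the
  # front/back trunk sensors with eyes open/closed.
  for (sensor in c("front", "back")) {
    for (eyes in c("open", "closed")) {
      cond <- sprintf("%s_%s", sensor, eyes)
      add(sprintf("ROM_entropy_ML_%s", cond), "ROM", "balance", "S", "ML",
          NA, cond)
      add(sprintf("ROM_entropy_AP_%s", cond), "ROM", "balance", "S", "AP",
          NA, cond)
      add(sprintf("ROM_entropy_VT_%s", cond), "ROM", "balance", "A", "VT",
          NA, cond)
      if (sensor == "back") {
        add(sprintf("ROM_entropy_All_%s", cond), "ROM", "balance", "S", NA,
            NA, cond)
      }
    }
  }

  # WAL (45, gait): trunk velocity irregularity (fuzzy entropy) plus
  # ankle resonance per axis, at slow/preferred/fast speeds.
  for (speed in c("slow", "preferred", "fast")) {
    add(sprintf("WAL_fuzzyen_vel_VT_%s", speed), "WAL", "gait", "S", "VT",
        NA, speed)
    add(sprintf("WAL_fuzzyen_vel_ML_%s", speed), "WAL", "gait", "A", "ML",
        NA, speed)
    add(sprintf("WAL_fuzzyen_vel_AP_%s", speed), "WAL", "gait", "R", "AP",
        NA, speed)
    for (s in sides) {
      add(sprintf("WAL_RF_VT_%s_%s", s, speed), "WAL", "gait", "S", "VT",
          s, speed)
      add(sprintf("WAL_MR_VT_%s_%s", s, speed), "WAL", "gait", "S", "VT",
          s, speed)
      add(sprintf("WAL_RF_ML_%s_%s", s, speed), "WAL", "gait", "A", "ML",
          s, speed)
      add(sprintf("WAL_MR_ML_%s_%s", s, speed), "WAL", "gait", "A", "ML",
          s, speed)
      add(sprintf("WAL_RF_AP_%s_%s", s, speed), "WAL", "gait", "R", "AP",
          s, speed)
      add(sprintf("WAL_MR_AP_%s_%s", s, speed), "WAL", "gait", "R", "AP",
          s, speed)
    }
  }

  # SPE (6, speech): prosodic features of the repeated /ta/ train.
  add("SPE_damping_ratio", "SPE", "speech", "S")
  add("SPE_RF", "SPE", "speech", "T")
  add("SPE_compensation_reg", "SPE", "speech", "R")
  add("SPE_peak_prominence", "SPE", "speech", "R")
  add("SPE_gap_reg", "SPE", "speech", "R")
  add("SPE_duration_reg", "SPE", "speech", "R")

  out <- do.call(rbind, rows)
  rownames(out) <- out$feature_id
  out
}

# Expected per-test feature counts (names in canonical test order).
taxonomyCounts <- function() {
  c(DDK = 20L, FNT = 20L, FIN = 20L, BAL = 14L, FOO = 14L, HST = 19L,
    ROM = 14L, WAL = 45L, SPE = 6L)
}
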