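# Small in-code fixtures shared across test files.

# feature set with planted group structure in selected tests/features
make_planted_fset <- function(n_control = 8, n_ataxic = 10, shift_tests = "ROM",
                              shift = 2, seed = 1) {
  set.seed(seed)
  meta <- featureTaxonomy()
  n <- n_control + n_ataxic
  ids <- sprintf("P%03d", seq_len(n))
  M <- matrix(rnorm(nrow(meta) * n), nrow = nrow(meta),
              dimnames = list(meta$feature_id, ids))
  grp <- c(rep("control", n_control), rep("ataxic", n_ataxic))
  sel <- meta$test %in% shift_tests
  M[sel, grp == "ataxic"] <- M[sel, grp == "ataxic"] + shift
  truth <- data.frame(
    subject_id = ids, group = grp,
    severity = ifelse(grp == "ataxic", 0.8, 0),
    row.names = ids
  )
  for (d in c("speech", "upper_limb", "lower_limb", "balance", "gait")) {
    truth[[d]] <- as.integer(grp == "ataxic")
  }
  coaFeatureSet(M, meta, truth)
}

# tiny deterministic truth table with SARA items
make_truth <- function(n_control = 4, n_ataxic = 6, seed = 3) {
  cfg <- cohortConfig(n_controls = n_control, n_ataxic = n_ataxic,
                      seed = seed)
  simulateCohort(cfg)$truth
}
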