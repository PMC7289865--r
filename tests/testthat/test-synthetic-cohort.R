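test_that("cohort configuration is validated", {
  expect_error(cohortConfig(n_controls = 1), "at least 2")
  expect_error(cohortConfig(domain_affect_prob = rep(1.5, 5)), "\\[0, 1\\]")
  expect_error(cohortConfig(star_mix = c(1, 1, 0, 0)), "summing to 1")
  expect_error(cohortConfig(severity_range = c(0.9, 0.1)), "ordered pair")
  cfg <- cohortConfig()
  expect_s3_class(cfg, "CohortConfig")
  expect_equal(cfg$n_controls + cfg$n_ataxic, 34)
})

test_that("cohort generation matches configured counts and is reproducible", {
  cfg <- cohortConfig(seed = 7)
  sim <- simulateCohort(cfg)
  expect_equal(nrow(sim$truth), 34)
  expect_equal(sum(sim$truth$group == "control"), 11)
  expect_equal(dim(featureMatrix(sim$features)), c(34, 172))
  # same config, same seed: identical outputs
  sim2 <- simulateCohort(cohortConfig(seed = 7))
  expect_identical(sim$truth, sim2$truth)
  expect_identical(featureMatrix(sim$features), featureMatrix(sim2$features))
  # a different seed changes the draw
  sim3 <- simulateCohort(cohortConfig(seed = 8))
  expect_false(identical(featureMatrix(sim$features),
                         featureMatrix(sim3$features)))
})

test_that("ground-truth labels are internally consistent", {
  sara <- coaStar:::saraItemTable()
  for (s in 1:5) {
    truth <- simulateCohort(cohortConfig(seed = s))$truth
    ctrl <- truth$group == "control"
    doms <- as.matrix(truth[, c("speech", "upper_limb", "lower_limb",
                                "balance", "gait")])
    items <- as.matrix(truth[, sara$item])
    # controls: severity 0, no domains, all SARA items 0
    expect_true(all(truth$severity[ctrl] == 0))
    expect_true(all(doms[ctrl, ] == 0))
    expect_true(all(items[ctrl, ] == 0))
    # ataxic subjects carry at least one domain label
    expect_true(all(rowSums(doms[!ctrl, , drop = FALSE]) >= 1))
    # domain_labels all-zero iff control
    expect_equal(unname(rowSums(doms) == 0), unname(ctrl))
    # item scores stay on their printed ranges
    expect_true(all(items >= 0 & items <= rep(sara$max, each = nrow(items))))
    # affected domains have a positive mapped item and vice versa
    for (d in unique(sara$domain)) {
      mapped <- items[, sara$item[sara$domain == d], drop = FALSE]
      expect_equal(as.integer(rowSums(mapped) > 0), unname(doms[, d]))
    }
  }
})

test_that("zero severity yields null group differences in feature mode", {
  ps <- c()
  for (s in 1:10) {
    sim <- simulateCohort(cohortConfig(seed = s, severity_range = c(0, 0)))
    M <- featureMatrix(sim$features)
    g <- sim$truth$group == "ataxic"
    ps <- c(ps, apply(M, 2, function(v) mwwTest(v[g], v[!g])))
  }
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("group effect size grows monotonically with severity", {
  med_es <- vapply(c(0.2, 0.5, 0.9), function(sev) {
    es <- vapply(1:30, function(s) {
      sim <- simulateCohort(cohortConfig(seed = s,
                                         severity_range = c(sev, sev)))
      M <- featureMatrix(sim$features)
      g <- sim$truth$group == "ataxic"
      median(abs(colMeans(M[g, ]) - colMeans(M[!g, ])))
    }, numeric(1))
    median(es)
  }, numeric(1))
  expect_true(all(diff(med_es) > 0))
})

test_that("raw-signal mode yields every test and condition per subject", {
  cfg <- cohortConfig(n_controls = 2, n_ataxic = 2, seed = 3,
                      mode = "raw_signals")
  sim <- simulateCohort(cfg)
  expect_length(sim$records, 4)
  recs <- sim$records[[3]]
  tests <- vapply(recs, function(r) r@test, character(1))
  expect_equal(sort(unique(tests)),
               sort(c("DDK", "FNT", "FIN", "BAL", "FOO", "HST", "ROM",
                      "WAL", "SPE")))
  counts <- table(tests)
  expect_equal(as.integer(counts[c("DDK", "BAL", "ROM", "WAL", "SPE")]),
               c(2L, 2L, 4L, 3L, 1L))
  # channel block integrity and protocol durations
  for (r in recs) {
    ch <- signalChannels(r)
    dur <- nrow(ch) / samplingRate(r)
    lim <- switch(r@test, SPE = 5, ROM = 30, WAL = 90, 15)
    expect_lte(dur, lim)
    expect_true(all(is.finite(ch)))
  }
  # deterministic regeneration
  sim2 <- simulateCohort(cfg)
  expect_identical(signalChannels(sim$records[[2]][[5]]),
                   signalChannels(sim2$records[[2]][[5]]))
})

test_that("perturbation is identity at severity zero and degrades STAR axes", {
  set.seed(31)
  base <- coaStar:::baseRepetitive("x", "FIN", "L",
                                   coaStar:::drawSubjectParams())
  expect_identical(perturbSignal(base, 0, c(0.25, 0.25, 0.25, 0.25)), base)
  expect_error(perturbSignal(base, 1.2, c(1, 0, 0, 0)), "severity")
  # rhythmicity-only: inter-tap CV strictly increases
  okR <- 0
  okS <- 0
  for (s in 1:20) {
    set.seed(s)
    b <- coaStar:::baseRepetitive("x", "FIN", "L",
                                  coaStar:::drawSubjectParams())
    p <- perturbSignal(b, 1, c(0, 0, 0, 1))
    cv0 <- rhythmicVariation(detectEvents(signalChannels(b)[, "acc_y"], 50))
    cv1 <- rhythmicVariation(detectEvents(signalChannels(p)[, "acc_y"], 50))
    okR <- okR + (cv1 > cv0)
    # stability-only on DDK: secondary/primary power ratio increases
    set.seed(100 + s)
    bd <- coaStar:::baseRepetitive("x", "DDK", "L",
                                   coaStar:::drawSubjectParams())
    pd <- perturbSignal(bd, 1, c(1, 0, 0, 0))
    ratio <- function(ch) (var(ch[, "acc_x"]) + var(ch[, "acc_z"])) /
      var(ch[, "acc_y"])
    okS <- okS + (ratio(signalChannels(pd)) > ratio(signalChannels(bd)))
  }
  expect_equal(okR, 20)
  expect_equal(okS, 20)
})

test_that("stability perturbation raises eyes-closed sway entropy", {
  ok <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    b <- coaStar:::baseRomberg("x", "back", "closed")
    p <- perturbSignal(b, 1, c(1, 0, 0, 0))
    e0 <- swayEntropy(list(b))
    e1 <- swayEntropy(list(p))
    sel <- !is.na(e0) & grepl("back_closed", names(e0)) &
      grepl("ML|AP|All", names(e0))
    ok <- ok + all(e1[sel] > e0[sel])
  }
  expect_gte(ok, 18)
})
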