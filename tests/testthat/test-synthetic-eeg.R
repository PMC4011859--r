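test_that("sim_config validates its inputs", {
  plan <- data.frame(label = "2", duration = 60)
  expect_s3_class(sim_config(plan), "sim_config")
  expect_error(sim_config(data.frame(label = "9", duration = 60)),
               "unknown stage label")
  expect_error(sim_config(data.frame(label = "1", duration = 9)),
               "below minimum")
  expect_error(sim_config(data.frame(label = "HFT", duration = 1)),
               "below minimum")
  expect_error(sim_config(plan, sampling_rate = 128), "160")
  expect_error(sim_config(plan, margin = 0.6), "margin")
  expect_error(sim_config(plan, artifact_plan = data.frame(
    kind = "movement", onset = 50, duration = 30)), "outside")
  expect_error(sim_config(plan, artifact_plan = data.frame(
    kind = c("movement", "grooming"), onset = c(5, 20),
    duration = c(20, 10))), "overlap")
})

test_that("identical config and seed give bit-identical output", {
  plan <- data.frame(label = c("baseline", "1"), duration = c(20, 30))
  a <- synthesize_recording(sim_config(plan, seed = 5))
  b <- synthesize_recording(sim_config(plan, seed = 5))
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$spikes, b$truth$spikes)
  expect_identical(a$truth$epochs, b$truth$epochs)
  expect_identical(a$record$activity_per_min, b$record$activity_per_min)
})

test_that("baseline segments stay below 200 uV with near-zero band power", {
  seg <- make_stage_segment("baseline", 60, seed = 3)
  expect_lt(max(abs(seg$trace)), 200)
  expect_true(all(seg$spikes$amplitude < 200))
  bp <- band_power(eeg_record(seg$trace, 250))
  expect_true(all(as.matrix(bp[, c("delta", "theta", "alpha",
                                   "sigma", "beta", "gamma")]) < 5))
})

test_that("HFT segments obey the published ISI and per-minute rate", {
  for (sd in 1:3) {
    seg <- make_stage_segment("HFT", 5, seed = sd)
    sp <- seg$spikes
    rate_equiv <- nrow(sp) / 5 * 60
    expect_gte(rate_equiv, 120)
    expect_lte(rate_equiv, 200)
    isis <- diff(sp$time) * 1000
    intra <- isis[isis < 100]          # within-burst intervals
    expect_true(all(intra >= 25 & intra <= 60))
    expect_true(all(sp$amplitude >= 300 & sp$amplitude <= 1000))
    expect_true(all(sp$duration_ms >= 20 & sp$duration_ms <= 40))
  }
})

test_that("unknown labels and short durations are rejected", {
  expect_error(make_stage_segment("6", 60), "unknown label")
  expect_error(make_stage_segment("1", 9), "below minimum")
})

test_that("stage plan arithmetic: epochs tile the recording without gaps", {
  plan <- data.frame(label = c("baseline", "2", "HFT", "3B"),
                     duration = c(60, 120, 5, 60))
  syn <- synthesize_recording(sim_config(plan, seed = 1))
  expect_equal(length(syn$record$samples), 245 * 250)
  ep <- syn$truth$epochs
  expect_equal(sum(ep$epoch_len == 10), 24)
  expect_equal(sum(ep$epoch_len), 245)
  expect_equal(ep$epoch_start, cumsum(c(0, head(ep$epoch_len, -1))))
})

test_that("activity channel follows the published per-stage ranges", {
  plan <- data.frame(label = c("1", "2", "HFT", "3A", "3B", "4", "5"),
                     duration = c(60, 60, 60, 60, 60, 60, 60))
  act <- make_activity_channel(plan, seed = 2)
  expect_length(act, 7)
  expect_equal(act[1:3], c(0L, 0L, 0L))
  expect_true(act[4] >= 0 && act[4] <= 8)
  expect_true(act[5] >= 20 && act[5] <= 120)
  expect_true(act[6] >= 20 && act[6] <= 80)
  expect_true(act[7] >= 30 && act[7] <= 60)
  expect_length(make_activity_channel(plan[0, ]), 0)
})

test_that("electrical artifacts are > 2 mV and < 20 ms", {
  rec <- eeg_record(rnorm(250 * 60, 0, 5), 250)
  res <- inject_artifact(rec, "electrical", 20, 3, seed = 4)
  tr <- detect_spikes(res$record)
  expect_gt(nrow(tr$spikes), 0)
  expect_true(all(tr$spikes$amplitude > 2000))
  expect_true(all(tr$spikes$duration_ms < 20))
})

test_that("grooming raises delta/theta/alpha only, within published caps", {
  rec <- eeg_record(rnorm(250 * 60, 0, 5), 250)
  before <- band_power(rec)
  res <- inject_artifact(rec, "grooming", 10, 40, seed = 7)
  after <- band_power(res$record)
  mid <- 3  # epoch fully inside the artifact window
  expect_lte(after$delta[mid], 700)
  expect_lte(after$theta[mid], 100)
  expect_lte(after$alpha[mid], 10)
  expect_gt(after$delta[mid], before$delta[mid] + 5)
  expect_gt(after$theta[mid], before$theta[mid] + 5)
  # sigma/beta/gamma unaffected
  expect_lt(abs(after$sigma[mid] - before$sigma[mid]), 1)
  expect_lt(abs(after$beta[mid] - before$beta[mid]), 1)
  expect_lt(abs(after$gamma[mid] - before$gamma[mid]), 1)
})

test_that("movement leaves the 0.5-80 Hz spectrum unchanged", {
  rec <- eeg_record(rnorm(250 * 60, 0, 5), 250)
  before <- band_power(rec)
  res <- inject_artifact(rec, "movement", 15, 20, seed = 9)
  slow <- detect_slow_deflections(res$record)
  expect_gt(nrow(slow), 0)
  after <- band_power(res$record, exclude_slow = slow)
  bands <- c("delta", "theta", "alpha", "sigma", "beta", "gamma")
  expect_true(all(abs(as.matrix(after[, bands]) -
                        as.matrix(before[, bands])) < 2.5, na.rm = TRUE))
  # paired activity counts in the published 20-80/min range
  act <- res$record$activity_per_min
  expect_true(any(act > 0))
  expect_true(all(act[act > 0] <= 80 & act[act > 0] >= 20))
})

test_that("artifact windows must lie inside the recording", {
  rec <- eeg_record(rnorm(250 * 30), 250)
  expect_error(inject_artifact(rec, "movement", 25, 10), "outside")
  expect_error(inject_artifact(rec, "grooming", 5, 10,
                               existing = data.frame(onset = 8,
                                                     duration = 10)),
               "overlap")
})

test_that("round trip: measured spike features lie in the published ranges", {
  # margin 0.15, the spec'd bound for this property
  rules <- stage_rule_table()
  plan <- data.frame(label = c("1", "2", "HFT", "3A", "3B", "4", "5"),
                     duration = c(30, 30, 10, 30, 30, 30, 30))
  syn <- synthesize_recording(sim_config(plan, margin = 0.15, seed = 2))
  tr <- detect_spikes(syn$record)
  sp <- tr$spikes
  tru <- syn$truth$spikes
  checked <- 0L
  for (i in seq_len(nrow(sp))) {
    j <- which.min(abs(tru$time - sp$peak_time[i]))
    if (abs(tru$time[j] - sp$peak_time[i]) > 0.05) next
    lab <- tru$label[j]
    if (lab == "baseline") next
    checked <- checked + 1L
    expect_gte(sp$amplitude[i], rules[lab, "amp_lo"])
    expect_lte(sp$amplitude[i], rules[lab, "amp_hi"])
    expect_gte(sp$duration_ms[i], rules[lab, "dur_lo"])
    expect_lte(sp$duration_ms[i], rules[lab, "dur_hi"])
  }
  expect_gt(checked, 100)
})

test_that("power containment: pure epoch band powers lie in table ranges", {
  fx <- fx_stagerec()
  rules <- stage_rule_table()
  cmp <- fx_compare(fx)
  f <- merge(cmp, fx$ana$features, by = "epoch_start")
  f <- f[f$pure & is.na(f$artifact), ]
  bands <- c("delta", "theta", "alpha", "sigma", "beta", "gamma")
  for (i in seq_len(nrow(f))) {
    lab <- f$label.truth[i]
    for (b in bands) {
      r <- unlist(rules[lab, paste0(b, c("_lo", "_hi"))])
      tol <- 0.1 * (r[2] - r[1])  # spike energy leaks across bands
      expect_gte(f[[b]][i], r[1] - tol)
      expect_lte(f[[b]][i], r[2] + tol)
    }
  }
})
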