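test_that("the shipped rule table reproduces every published cell", {
  r <- stage_rule_table()
  # golden copy of the printed stage table, frozen here independently
  golden <- list(
    "1"   = c(200, 600, 100, 200, 400, 1400, 20, 35,
              8, 12, 4, 7, 0.7, 1.5, 0.3, 0.9, 0.2, 0.5, 0.4, 0.8, 0, 0),
    "2"   = c(200, 1500, 100, 400, 450, 1500, 40, 60,
              25, 50, 5, 15, 3, 5, 1, 3, 1, 3, 1, 2, 0, 0),
    "HFT" = c(300, 1000, 20, 40, 25, 60, 120, 200,
              5, 10, 4, 8, 10, 20, 8, 16, 8, 15, 15, 90, 0, 0),
    "3A"  = c(300, 700, 50, 150, 100, 600, 40, 60,
              10, 15, 6, 12, 8, 15, 8, 13, 6, 12, 15, 70, 0, 8),
    "3B"  = c(400, 900, 200, 500, 180, 320, 30, 60,
              10, 20, 15, 30, 8, 14, 5, 9, 10, 20, 18, 90, 20, 120),
    "4"   = c(400, 700, 200, 400, 200, 800, 30, 70,
              5, 20, 15, 20, 5, 10, 4, 8, 8, 15, 15, 50, 20, 80),
    "5"   = c(300, 700, 50, 200, 50, 200, 80, 140,
              8, 15, 5, 15, 4, 8, 3, 7, 5, 12, 8, 30, 30, 60))
  cols <- c("amp_lo", "amp_hi", "dur_lo", "dur_hi", "isi_lo", "isi_hi",
            "rate_lo", "rate_hi", "delta_lo", "delta_hi", "theta_lo",
            "theta_hi", "alpha_lo", "alpha_hi", "sigma_lo", "sigma_hi",
            "beta_lo", "beta_hi", "gamma_lo", "gamma_hi", "act_lo",
            "act_hi")
  for (st in names(golden)) {
    expect_equal(unname(unlist(r[st, cols])), golden[[st]],
                 info = paste("stage", st))
  }
  expect_match(r["2", "behavior"], "Hunched")
  expect_error(stage_rule_table("/no/such/rules.csv"), "not found")
})

feat_row <- function(delta = 1, theta = 1, alpha = 1, sigma = 1, beta = 1,
                     gamma = 1, spike_count = 0, mean_amplitude = NA,
                     mean_duration = NA, mean_isi = NA, rate = 0,
                     activity = 0, epoch_start = 0) {
  data.frame(epoch_start = epoch_start, delta = delta, theta = theta,
             alpha = alpha, sigma = sigma, beta = beta, gamma = gamma,
             total = delta + theta + alpha + sigma + beta + gamma,
             kept_frac = 1, spike_count = spike_count,
             mean_amplitude = mean_amplitude,
             mean_duration = mean_duration, mean_isi = mean_isi,
             rate = rate, activity = activity)
}

test_that("artifact rules match the published criteria", {
  el <- classify_artifact(
    feat_row(spike_count = 1, mean_amplitude = 2500, mean_duration = 10),
    spikes = data.frame(amplitude = 2500, duration_ms = 10))
  expect_equal(el, "artifact_electrical")

  gr <- classify_artifact(feat_row(delta = 500, theta = 60, alpha = 5,
                                   sigma = 1, beta = 1, gamma = 1))
  expect_equal(gr, "artifact_grooming")

  mv <- classify_artifact(feat_row(activity = 40),
                          slow_events = data.frame(onset = 2, offset = 5))
  expect_equal(mv, "artifact_movement")

  expect_true(is.na(classify_artifact(feat_row())))
  # precedence: a >2 mV short spike wins even with grooming-like powers
  both <- classify_artifact(
    feat_row(delta = 500, theta = 60, alpha = 5),
    spikes = data.frame(amplitude = 2600, duration_ms = 8))
  expect_equal(both, "artifact_electrical")
})

test_that("stage scoring ranks the matching stage first", {
  rules <- stage_rule_table()
  mid <- function(st, f) mean(unlist(rules[st, paste0(f, c("_lo", "_hi"))]))
  f1 <- feat_row(delta = mid("1", "delta"), theta = mid("1", "theta"),
                 alpha = mid("1", "alpha"), sigma = mid("1", "sigma"),
                 beta = mid("1", "beta"), gamma = mid("1", "gamma"),
                 spike_count = 5, mean_amplitude = mid("1", "amp"),
                 mean_duration = mid("1", "dur"), mean_isi = mid("1", "isi"),
                 rate = mid("1", "rate"), activity = 0)
  s <- score_stage(f1, rules)
  expect_equal(names(which.max(s)), "1")
  expect_equal(unname(s["1"]), 1)

  f3b <- feat_row(delta = 15, theta = 20, alpha = 10, sigma = 7, beta = 15,
                  gamma = 50, spike_count = 8, mean_amplitude = 600,
                  mean_duration = 300, mean_isi = 250, rate = 45,
                  activity = 60)
  expect_equal(names(which.max(score_stage(f3b, rules))), "3B")
})

test_that("ties break to the previous label, else the higher stage", {
  rules <- stage_rule_table()
  # features hitting exactly the same 8 of 11 ranges for 3A and 3B
  tie <- feat_row(delta = 12, theta = 13, alpha = 10, sigma = 8.5,
                  beta = 11, gamma = 30, spike_count = 8,
                  mean_amplitude = 500, mean_duration = 175,
                  mean_isi = 250, rate = 50, activity = 15)
  s <- score_stage(tie, rules)
  expect_equal(s[["3A"]], s[["3B"]])
  expect_equal(max(s), s[["3A"]])

  mid <- function(st, f) mean(unlist(rules[st, paste0(f, c("_lo", "_hi"))]))
  a3 <- feat_row(delta = mid("3A", "delta"), theta = mid("3A", "theta"),
                 alpha = mid("3A", "alpha"), sigma = mid("3A", "sigma"),
                 beta = mid("3A", "beta"), gamma = mid("3A", "gamma"),
                 spike_count = 8, mean_amplitude = mid("3A", "amp"),
                 mean_duration = mid("3A", "dur"),
                 mean_isi = mid("3A", "isi"), rate = mid("3A", "rate"),
                 activity = 4)
  tie$epoch_start <- 10
  out <- classify_epochs(rbind(a3, tie), rules, smoothing_len = 1)
  expect_equal(out$label, c("3A", "3A"))
  # without a 3A predecessor the higher stage wins
  out2 <- classify_epochs(tie[, ], rules, smoothing_len = 1)
  expect_equal(out2$label, "3B")
})

test_that("epoch recovery >= 90% on margin-0.2 synthetic data", {
  fx <- fx_stagerec()
  cmp <- fx_compare(fx)
  acc <- mean(cmp$label.truth == cmp$label.pred)
  expect_gte(acc, 0.9)
})

test_that("an all-baseline record is labeled baseline throughout", {
  syn <- synthesize_recording(sim_config(
    data.frame(label = "baseline", duration = 120), seed = 6))
  ana <- analyze_record(syn$record)
  expect_true(all(ana$epochs$label == "baseline"))
  expect_equal(nrow(ana$hft), 0)
  expect_equal(nrow(ana$transitions), 0)
})

test_that("artifact recall >= 95% and artifact epochs are excluded", {
  for (fx in fx_artifacts()) {
    cmp <- fx_compare(fx)
    art <- !is.na(cmp$artifact)
    hit <- cmp$label.pred == paste0("artifact_", cmp$artifact)
    expect_gte(sum(art & hit) / sum(art), 0.95)
    expect_true(all(cmp$excluded[art & hit]))
    # excluded epochs carry no stage label and no stage score mass
    sc <- attr(fx$ana$epochs, "scores")
    expect_true(all(is.na(sc[fx$ana$epochs$excluded, ])))
  }
})

test_that("HFT detection: one interval covering >= 80% of the segment", {
  for (fx in fx_fig5()) {
    hft <- fx$ana$hft
    expect_equal(nrow(hft), 1)
    cov <- (min(hft$end, 75) - max(hft$start, 70)) / 5
    expect_gte(cov, 0.8)
  }
  # stage-2 spiking (ISI 450-1500 ms) never qualifies
  syn2 <- synthesize_recording(sim_config(
    data.frame(label = "2", duration = 120), seed = 3))
  ana2 <- analyze_record(syn2$record)
  expect_equal(nrow(ana2$hft), 0)
  empty <- detect_spikes(eeg_record(numeric(2500), 250))
  expect_equal(nrow(detect_hft(empty)), 0)
})

test_that("transition markers appear once, in order, at the boundaries", {
  for (fx in fx_fig5()) {
    tr <- fx$ana$transitions
    ncs <- tr[tr$marker == "ncs_to_cms", ]
    expect_equal(nrow(ncs), 1)
    # between the last stage-2 epoch (60-70 s) and the first 3A/3B epoch
    expect_gte(ncs$time, 60)
    expect_lte(ncs$time, 80)
    ab <- tr[tr$marker == "stage3a_to_3b", ]
    expect_equal(nrow(ab), 1)
    # within one epoch of the 3A/3B boundary at 115 s
    expect_gte(ab$time, 100)
    expect_lte(ab$time, 120)
    expect_lt(ncs$time, ab$time)  # monotone marker ordering
  }
  # an all-NCS recording yields no markers
  syn <- synthesize_recording(sim_config(
    data.frame(label = c("1", "2"), duration = c(60, 60)), seed = 2))
  ana <- analyze_record(syn$record)
  expect_equal(nrow(ana$transitions), 0)
})
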