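test_that("diary validation", {
  iv <- data.frame(start = c(0, 100), end = c(100, 200), stage = c(1, 3))
  expect_s3_class(diary_rld(iv), "seizure_diary")
  expect_error(diary_rld(data.frame(start = 0, end = 0, stage = 1)),
               "end > start")
  expect_error(diary_rld(data.frame(start = c(0, 50), end = c(100, 150),
                                    stage = c(1, 2))), "overlap")
  expect_error(diary_rld(data.frame(start = 0, end = 10, stage = 7)),
               "0..5")
})

test_that("epoch score is the highest stage reached in the epoch", {
  # 3 min of stages 1-2 then 2 min of stage 3 -> scores 3
  d <- diary_rld(data.frame(start = c(0, 60, 180), end = c(60, 180, 300),
                            stage = c(1, 2, 3)))
  expect_equal(racine_epoch_score(d, 0), 3L)
  # seizure-free epoch -> 0
  d2 <- diary_rld(data.frame(start = 600, end = 700, stage = 2))
  expect_equal(racine_epoch_score(d2, 0), 0L)
  # a 10-s stage-5 interval amid stage 2 dominates
  d3 <- diary_rld(data.frame(start = c(0, 100, 110),
                             end = c(100, 110, 300), stage = c(2, 5, 2)))
  expect_equal(racine_epoch_score(d3, 0), 5L)
  expect_error(racine_epoch_score(d3, 1e6), "outside")
})

test_that("SE window follows the protocol's index seizure", {
  d <- diary_rld(data.frame(start = c(0, 80 * 60), end = c(80 * 60, 90 * 60),
                            stage = c(2, 5)))
  w <- se_window(d)
  expect_true(w$achieved)
  expect_equal(c(w$start, w$end) / 60, c(80, 200))
  expect_equal(w$end - w$start, 7200)

  d2 <- diary_rld(data.frame(start = 0, end = 600, stage = 3))
  expect_false(se_window(d2)$achieved)
  expect_error(cumulative_severity(d2, se_window(d2)), "not achieved")

  d3 <- seizure_diary("m", "SHD", data.frame(start = 25 * 60, end = 30 * 60,
                                             stage = 3))
  w3 <- se_window(d3)
  expect_equal(c(w3$start, w3$end) / 60, c(25, 145))
})

test_that("cumulative severity integrates time in CMS and stage 5", {
  full5 <- diary_rld(data.frame(start = 0, end = 7200, stage = 5))
  cs <- cumulative_severity(full5, se_window(full5))
  expect_equal(cs$time_in_cms_s, 7200)
  expect_equal(cs$time_in_stage5_s, 7200)
  expect_equal(cs$severity_score, 24 * 5)

  ncs <- seizure_diary("m", "SHD",
                       data.frame(start = c(0, 10), end = c(10, 7210),
                                  stage = c(3, 2)))
  cs2 <- cumulative_severity(ncs, se_window(ncs))
  expect_equal(cs2$time_in_cms_s, 10)
  expect_equal(cs2$time_in_stage5_s, 0)
  expect_equal(cs2$severity_score, 3 + 23 * 2)

  half <- diary_rld(data.frame(start = c(0, 3600), end = c(3600, 7200),
                               stage = c(5, 2)))
  expect_equal(cumulative_severity(half, se_window(half))$time_in_cms_s,
               3600)
})

test_that("diazepam/death clip the scored window", {
  d <- diary_rld(data.frame(start = 0, end = 7200, stage = 5),
                 dz = 3750)
  cs <- cumulative_severity(d, se_window(d))
  expect_equal(cs$time_in_cms_s, 3750)
  # 12 full epochs + one 150-s partial epoch still scoring stage 5
  expect_equal(cs$severity_score, 13 * 5)
})

test_that("severity is monotone in stage upgrades", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 24
    st <- sample(0:5, n, replace = TRUE)
    st[1] <- 5
    iv <- data.frame(start = 300 * (0:(n - 1)), end = 300 * (1:n),
                     stage = st)
    d <- diary_rld(iv)
    w <- se_window(d)
    cs <- cumulative_severity(d, w)
    expect_gte(cs$time_in_cms_s, cs$time_in_stage5_s)
    expect_lte(cs$time_in_cms_s, 7200)
    k <- sample(which(st < 5), 1)
    iv2 <- iv
    iv2$stage[k] <- iv2$stage[k] + 1L
    cs2 <- cumulative_severity(diary_rld(iv2), w)
    expect_gte(cs2$severity_score, cs$severity_score)
  }
})

test_that("classifier output converts to a behavioral diary", {
  cls <- data.frame(epoch_start = seq(0, 50, 10),
                    label = c("baseline", "2", "artifact_movement", "3A",
                              "3B", "5"),
                    excluded = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  d <- diary_from_epochs(cls, protocol = "RLD")
  expect_equal(d$intervals$stage, c(0L, 2L, 3L, 5L))
  expect_equal(d$intervals$start, c(0, 10, 30, 50))
  expect_equal(stage_to_behavioral(c("baseline", "HFT", "3A", "3B", "5")),
               c(0L, 2L, 3L, 3L, 5L))
})
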