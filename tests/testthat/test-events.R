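test_that("noise-free trials yield heel strikes within one sample of truth", {
  sim <- fixture_clean_trial()
  ev <- detect_gait_events(sim$trial)
  dt <- 1 / sampling_rate(sim$trial)
  for (side in c("left", "right")) {
    hs_err <- vapply(ev[[side]]$heel_strikes,
                     function(h) min(abs(sim$truth$heel_strikes[[side]] - h)), 0)
    expect_lte(max(hs_err), dt + 1e-12)
    to_err <- vapply(ev[[side]]$toe_offs,
                     function(h) min(abs(sim$truth$toe_offs[[side]] - h)), 0)
    expect_lte(max(to_err), dt + 1e-12)
  }
})

test_that("a 240 s trial at ~1.1 s stride time gives ~218 strides per foot", {
  sim <- fixture_clean_trial()
  ev <- detect_gait_events(sim$trial)
  for (side in c("left", "right")) {
    n_det <- length(ev[[side]]$heel_strikes)
    n_true <- length(sim$truth$heel_strikes[[side]])
    expect_lte(abs(n_det - n_true), 2)  # edge cycles only
    expect_gt(n_det, 210)
    expect_lt(n_det, 226)
  }
})

test_that("events alternate HS/TO within each foot and are increasing", {
  ev <- fixture_short_events()
  for (side in c("left", "right")) {
    hs <- ev[[side]]$heel_strikes
    to <- ev[[side]]$toe_offs
    expect_false(is.unsorted(hs, strictly = TRUE))
    expect_false(is.unsorted(to, strictly = TRUE))
    merged <- sort(c(hs, to))
    lab <- c(rep("HS", length(hs)), rep("TO", length(to)))[order(c(hs, to))]
    expect_true(all(lab[-1] != lab[-length(lab)]))
  }
  expect_error(gait_events(list(heel_strikes = c(1, 2), toe_offs = 1.5),
                           ev$right), "fewer than 3")
})

test_that("non-walking input raises an insufficient-data error", {
  sim <- fixture_short_trial()
  flat <- sim$trial
  flat$channels[, "left_foot_gyro_pitch_dps"] <- 0
  flat$channels[, "right_foot_gyro_pitch_dps"] <- 0
  expect_error(detect_gait_events(flat), "walking")
})

test_that("detection still works under default measurement noise", {
  sim <- simulate_trial(trial_config(duration_s = 60, seed = 5,
                                     full_channels = FALSE))
  ev <- detect_gait_events(sim$trial)
  expect_equal(length(ev$right$heel_strikes),
               length(sim$truth$heel_strikes$right), tolerance = 0.05)
  err <- vapply(ev$right$heel_strikes,
                function(h) min(abs(sim$truth$heel_strikes$right - h)), 0)
  expect_lt(stats::median(err), 0.05)  # within 50 ms under sensor noise
})
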