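test_that("Hurst estimates are affine-invariant and well-formed", {
  x <- simulate_fgn(512, 0.8, seed = 4)
  e1 <- estimate_hurst(x)
  e2 <- estimate_hurst(5 * x - 20)
  expect_equal(e1$H_hat, e2$H_hat, tolerance = 1e-8)
  expect_gt(e1$H_hat, 0); expect_lt(e1$H_hat, 1)
  expect_lte(e1$ci[1], e1$H_hat); expect_gte(e1$ci[2], e1$H_hat)
  expect_equal(e1$n, 512)
  expect_error(estimate_hurst(rnorm(32)), "short")
  expect_error(estimate_hurst(rep(1, 100)), "constant")
  expect_error(estimate_hurst(c(rnorm(99), NA)), "finite")
})

test_that("a strictly alternating series is identified as anti-persistent", {
  x <- rep(c(1, -1), 64)
  expect_lt(estimate_hurst(x)$H_hat, 0.5)
})

test_that("recovery bias stays below 0.05 at n = 1024 across the H range", {
  for (H in c(0.3, 0.5, 0.7, 0.9)) {
    hats <- vapply(1:20, function(i) {
      estimate_hurst(simulate_fgn(1024, H, seed = 4000 + 100 * H + i))$H_hat
    }, 0)
    expect_lt(abs(mean(hats) - H), 0.05)
  }
})

test_that("shuffling a persistent series returns estimates to white noise", {
  hats <- vapply(1:20, function(i) {
    x <- simulate_fgn(1024, 0.9, seed = 600 + i)
    estimate_hurst(shuffle_surrogate(x, seed = i))$H_hat
  }, 0)
  expect_equal(mean(hats), 0.5, tolerance = 0.05)
})

test_that("stride-series Hurst runs per side and pooled with surrogates", {
  tab <- fixture_short_table()  # 60 s: ~54 strides, too short per side
  expect_error(stride_series_hurst(tab, sides = "left"), "short")
  sim <- fixture_clean_trial()
  ev <- detect_gait_events(sim$trial)
  tab2 <- compute_gait_parameters(ev, sim$trial)
  hs <- stride_series_hurst(tab2)
  expect_setequal(unique(hs$side), c("left", "right", "pooled"))
  expect_setequal(unique(hs$variable), c("stride time", "stride length"))
  expect_true(all(hs$H_hat > 0 & hs$H_hat < 1))
  expect_true(all(hs$ci_lo <= hs$H_hat & hs$H_hat <= hs$ci_hi))
  # persistent input: originals clearly above their shuffled surrogates
  expect_gt(mean(hs$H_hat - hs$H_shuffled), 0.1)
})

test_that("end-to-end stride-time H recovery within 0.08 at ~218 strides", {
  hats <- vapply(c(42, 7, 123, 9, 55), function(sd) {
    sim <- simulate_trial(trial_config(noise_scale = 0, seed = sd,
                                       full_channels = FALSE))
    ev <- detect_gait_events(sim$trial)
    estimate_hurst(diff(ev$right$heel_strikes))$H_hat
  }, 0)
  expect_lt(abs(mean(hats) - 0.9), 0.08)
})
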