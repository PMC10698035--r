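test_that("centering applies the min/range formula exactly", {
  expect_equal(center_series(c(0, 2)), c(-1, 1))
  expect_equal(center_series(c(1, 3, 5)), c(-2, 0, 2))
  expect_warning(out <- center_series(c(5, 5, 5)), "constant")
  expect_equal(out, c(0, 0, 0))
  x <- rnorm(50)
  xc <- center_series(x)
  expect_equal(max(xc), -min(xc), tolerance = 1e-9)
})

test_that("cycle normalization preserves endpoints and affine signals", {
  expect_length(normalize_cycle(rnorm(200)), 100)
  ramp <- seq(0, 1, length.out = 73)
  out <- normalize_cycle(ramp, 100)
  expect_equal(out, seq(0, 1, length.out = 100))
  expect_equal(out[c(1, 100)], ramp[c(1, 73)])
  # band-limited round trip: up to 100 and back to 50
  sm <- sin(2 * pi * (0:49) / 49)
  back <- normalize_cycle(normalize_cycle(sm, 100), 50)
  expect_lt(max(abs(back - sm)), 1e-6)
  expect_error(normalize_cycle(rnorm(10), 1), "n")
  expect_error(normalize_cycle(1), "short")
})

test_that("segment phase tracks the analytic phase of a sinusoid", {
  x <- cos(2 * pi * (0:999) / 100)  # 10 full periods
  ph <- segment_phase(x, pad = 0)   # unpadded transform is exact here
  expect_equal(ph$phi[1], 0, tolerance = 1e-9)
  expect_equal(ph$phi[26], 90, tolerance = 1)  # quarter period
  # winding: 360 degrees per period
  unwrapped <- ph$phi + 360 * c(0, cumsum(diff(ph$phi) < -180))
  expect_equal(diff(unwrapped[c(1, 901)]), 9 * 360, tolerance = 2)
  expect_true(all(ph$phi > -180 & ph$phi <= 180))
  expect_error(segment_phase(rep(1, 100)), "constant")
  expect_error(segment_phase(1:4), "short")
})

test_that("relative phase identifies in-phase, anti-phase, and quarter lag", {
  fs <- 100
  t <- seq(0, 40, by = 1 / fs)
  f <- function(lag) cos(2 * pi * (t - lag)) + 0.15 * cos(4 * pi * (t - lag) - 1)
  starts <- 1:39
  expect_equal(crp_series(f(0), f(0), starts, fs)$phi_mean, 0, tolerance = 1e-6)
  expect_equal(crp_series(f(0), f(0.5), starts, fs)$phi_mean, 180,
               tolerance = 2)
  expect_equal(crp_series(f(0), f(0.25), starts, fs)$phi_mean, 90,
               tolerance = 2)
  res <- crp_series(f(0), f(0.5), starts, fs)
  expect_equal(ncol(res$cycles), 100)
  expect_false(res$anomalous)
  expect_error(crp_series(f(0), f(0.5), numeric(0), fs), "cycle")
  expect_error(crp_series(f(0), f(0.5)[-1], starts, fs), "equal length")
})

test_that("swapping sides negates the relative phase (mod 360)", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  r <- cos(2 * pi * t) + 0.1 * cos(4 * pi * t - 0.7)
  l <- cos(2 * pi * (t - 0.31)) + 0.1 * cos(4 * pi * (t - 0.31) - 0.7)
  starts <- 1:29
  a <- crp_series(r, l, starts, fs)
  b <- crp_series(l, r, starts, fs)
  d <- (a$cycles + b$cycles) %% 360
  d <- pmin(d, 360 - d)
  expect_lt(max(d), 1e-6)
})

test_that("relative phase is invariant to common scaling and offset", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  r <- cos(2 * pi * t); l <- cos(2 * pi * (t - 0.25))
  starts <- 1:29
  base <- crp_series(r, l, starts, fs)$phi_mean
  scaled <- crp_series(7 * r + 3, 7 * l + 3, starts, fs)$phi_mean
  expect_equal(scaled, base, tolerance = 1e-9)
})

test_that("anti-phase synthetic trials give 180 degrees on all segment pairs", {
  sim <- fixture_short_trial()
  ev <- fixture_short_events()
  for (seg in c("thigh", "shank", "foot")) {
    res <- trial_crp(sim$trial, seg, events = ev)
    expect_equal(res$phi_mean, 180, tolerance = 2)
    expect_false(res$anomalous)
  }
})

test_that("trials far from anti-phase are flagged anomalous", {
  cfg <- trial_config(duration_s = 60, noise_scale = 0, seed = 9,
                      phase_offset = 0.35, full_channels = FALSE)
  sim <- simulate_trial(cfg)
  res <- trial_crp(sim$trial, "thigh")
  expect_gt(abs(res$phi_mean - 180), 20)
  expect_true(res$anomalous)
})
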