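test_that("AMI is maximal at lag 0 and near zero for iid noise", {
  set.seed(1)
  x <- rnorm(10000)
  a <- average_mutual_information(x, 20)
  # equiprobable 16-bin marginal entropy = log2(16) bits at lag 0
  expect_equal(a$ami[1], 4, tolerance = 1e-6)
  expect_lt(max(a$ami[-1]), 0.05)
  expect_error(average_mutual_information(rep(2, 100), 5), "constant")
  expect_error(average_mutual_information(rnorm(20), 50), "short")
})

test_that("AMI first minimum of a sinusoid falls near the quarter period", {
  set.seed(3)
  x <- sin(2 * pi * (1:4000) / 100) + rnorm(4000, 0, 0.05)
  a <- average_mutual_information(x, 60)
  expect_equal(a$rule, "first_minimum")
  expect_gte(a$tau, 23)
  expect_lte(a$tau, 27)
})

test_that("delay embedding has the right shape and geometry", {
  expect_equal(dim(delay_embed(1:10, 3, 2)), c(6, 3))
  expect_equal(delay_embed(1:5, 1, 1)[, 1], 1:5)
  expect_error(delay_embed(1:10, 6, 2), "short")
  # sinusoid embedded at quarter-period delay traces a circle
  x <- sin(2 * pi * (1:2025) / 100)
  e <- delay_embed(x, 2, 25)  # 20 whole periods after embedding
  r <- sqrt(rowSums(sweep(e, 2, colMeans(e))^2))
  expect_lt(max(abs(r - mean(r))) / mean(r), 0.01)
})

test_that("FNN selects dimension 2 for a limit cycle and 3 for Lorenz", {
  f <- false_nearest_neighbors(sin(2 * pi * (1:4000) / 100), tau = 25,
                               max_dim = 6)
  expect_equal(f$dim, 2)
  xl <- fixture_lorenz_x()
  a <- average_mutual_information(xl, 100)
  fl <- false_nearest_neighbors(xl[1:4000], a$tau, max_dim = 6)
  expect_equal(fl$dim, 3)
  expect_error(false_nearest_neighbors(rnorm(40), 5, max_dim = 8), "short")
})

test_that("a noise-free sinusoid has a vanishing largest Lyapunov exponent", {
  x <- sin(2 * pi * (1:20000) / 220)
  w <- wolf_lle(delay_embed(x, 2, 55), fs = 200)
  expect_lt(abs(w$lambda1), 0.05)
  expect_true(all(w$diagnostics$d0 > 0))
  expect_true(all(w$diagnostics$dt_s > 0))
})

test_that("Wolf agrees with an independent Benettin oracle on Lorenz", {
  xl <- fixture_lorenz_x()
  a <- average_mutual_information(xl, 100)
  traj <- delay_embed(xl, 3, a$tau)
  # evolution time ~0.2 time units (a quarter of the mean orbital period)
  w <- wolf_lle(traj, fs = 50, evolve = 10)
  oracle <- fixture_lorenz_lambda1_benettin()
  expect_equal(oracle, 0.906, tolerance = 0.02)  # literature value
  expect_lt(abs(w$lambda1 - oracle) / oracle, 0.15)
})

test_that("lambda1 is exactly invariant to trajectory scaling and translation", {
  xl <- fixture_lorenz_x()
  traj <- delay_embed(xl[1:6000], 3, 9)
  w1 <- wolf_lle(traj, fs = 50)
  w2 <- wolf_lle(2 * traj, fs = 50)
  w3 <- wolf_lle(traj + 100, fs = 50)
  expect_identical(w1$lambda1, w2$lambda1)
  expect_equal(w1$lambda1, w3$lambda1, tolerance = 1e-6)
})

test_that("lambda1 grows with the noise level of a perturbed sinusoid", {
  levels <- c(0.01, 0.04, 0.15, 0.5, 2)
  seeds <- 1:20
  lam <- sapply(seq_along(levels), function(a) {
    vapply(seeds, function(s) {
      set.seed(1000 * a + s)
      x <- sin(2 * pi * (1:3000) / 110) + rnorm(3000, 0, levels[a])
      wolf_lle(delay_embed(x, 2, 27), fs = 200)$lambda1
    }, 0)
  })
  rc <- cor(rep(levels, each = length(seeds)), as.vector(lam),
            method = "spearman")
  expect_gt(rc, 0.9)
  expect_true(all(diff(colMeans(lam)) > 0))
})

test_that("segment-angle lambda1 is small, positive, and consistent across trials", {
  lam <- function(sdv, seeds) vapply(seeds, function(s) {
    tr <- simulate_trial(trial_config(duration_s = 60, seed = s,
                                      noise_scale = 0, stride_time_sd = sdv,
                                      full_channels = FALSE))$trial
    trial_lle(tr, downsample = 4)$lambda1
  }, 0)
  low <- lam(0.005, 1:3)
  high <- lam(0.06, 11:13)
  expect_true(all(low > 0) && all(high > 0))
  expect_true(all(low < 5) && all(high < 5))  # "rather small" values
  spread <- abs(mean(high) - mean(low))
  expect_lt(sd(low), spread)
  expect_lt(sd(high), spread)
})
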