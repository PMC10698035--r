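test_that("fGn autocorrelation matches the closed form", {
  expect_equal(fgn_autocorrelation(0.5, 1), 0)      # white noise
  expect_equal(fgn_autocorrelation(1.0, 1), 1)      # 1/2 (4 - 2 + 0)
  expect_equal(fgn_autocorrelation(0.9, 1), 0.5 * (2^1.8 - 2),
               tolerance = 1e-12)                   # ~0.7411
  expect_equal(fgn_autocorrelation(0.3, 0), 1)
  # anti-persistent: negative lag-1 correlation
  expect_lt(fgn_autocorrelation(0.1, 1), 0)
  expect_error(fgn_autocorrelation(1.2, 1), "H")
  expect_error(fgn_autocorrelation(0, 1), "H")
  expect_error(fgn_autocorrelation(0.5, -1), "lag")
})

test_that("simulated fGn reproduces the theoretical lag-1 autocovariance", {
  # Monte-Carlo oracle: the generator has known zero mean, so the lag-1
  # autocorrelation is estimated without mean subtraction (centering by the
  # sample mean biases persistent series far downward)
  lag1 <- function(H, reps = 200, n = 2048) {
    mean(vapply(seq_len(reps), function(i) {
      x <- simulate_fgn(n, H, seed = 1000 + i)
      sum(x[-1] * x[-n]) / sum(x^2)
    }, 0))
  }
  expect_lt(abs(lag1(0.5)), 0.01)
  expect_lt(abs(lag1(0.9) - fgn_autocorrelation(0.9, 1)), 0.02)
})

test_that("fGn simulation is deterministic given a seed and validates input", {
  expect_identical(simulate_fgn(512, 0.7, seed = 5),
                   simulate_fgn(512, 0.7, seed = 5))
  expect_false(identical(simulate_fgn(512, 0.7, seed = 5),
                         simulate_fgn(512, 0.7, seed = 6)))
  x <- simulate_fgn(256, 0.6, sigma = 2.5, mean = 10, seed = 1)
  expect_length(x, 256)
  expect_error(simulate_fgn(1, 0.5), "n")
  expect_error(simulate_fgn(100, 1.5), "H")
  expect_error(simulate_fgn(100, 0.5, sigma = 0), "sigma")
})

test_that("shuffle surrogates permute exactly and deterministically", {
  x <- simulate_fgn(300, 0.9, seed = 2)
  s <- shuffle_surrogate(x, seed = 11)
  expect_identical(sort(s), sort(x))
  expect_false(identical(s, x))
  expect_identical(s, shuffle_surrogate(x, seed = 11))
  expect_error(shuffle_surrogate(1), "2 values")
})
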