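# Shared, lazily computed fixtures (built once per test run).

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A noise-free standard-length trial with ground truth (lean channel set).
fixture_clean_trial <- function() {
  memo("clean_trial", simulate_trial(
    trial_config(noise_scale = 0, seed = 42, full_channels = FALSE)))
}

# A short noise-free trial for fast event/parameter checks.
fixture_short_trial <- function() {
  memo("short_trial", simulate_trial(
    trial_config(duration_s = 60, noise_scale = 0, seed = 7,
                 full_channels = FALSE)))
}

fixture_short_events <- function() {
  memo("short_events", detect_gait_events(fixture_short_trial()$trial))
}

fixture_short_table <- function() {
  memo("short_table", compute_gait_parameters(fixture_short_events(),
                                              fixture_short_trial()$trial))
}

# Lorenz x-coordinate (standard parameters), transient removed; dt = 0.02.
fixture_lorenz_x <- function() {
  memo("lorenz_x", {
    lorenz <- function(t, y, p) {
      list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
             y[1] * y[2] - 8 / 3 * y[3]))
    }
    out <- deSolve::ode(c(1, 1, 20), seq(0, 330, by = 0.02), lorenz, NULL,
                        method = "ode45", atol = 1e-9, rtol = 1e-9)
    out[-(1:1500), 2]
  })
}

# Independent Benettin (tangent-space) oracle for the Lorenz largest
# Lyapunov exponent: integrates the variational equations alongside the
# flow, renormalizing the tangent vector at fixed intervals.
fixture_lorenz_lambda1_benettin <- function() {
  memo("lorenz_benettin", {
    f <- function(t, y, p) {
      x <- y[1:3]; v <- y[4:6]
      J <- matrix(c(-10, 10, 0,
                    28 - x[3], -1, -x[1],
                    x[2], x[1], -8 / 3), 3, 3, byrow = TRUE)
      list(c(10 * (x[2] - x[1]), x[1] * (28 - x[3]) - x[2],
             x[1] * x[2] - 8 / 3 * x[3], J %*% v))
    }
    y <- c(1, 1, 20, 1, 0, 0)
    S <- 0; dt <- 0.5; burn <- 40; total <- 640
    for (i in seq_len(total)) {
      o <- deSolve::ode(y, c(0, dt), f, NULL, method = "ode45",
                        atol = 1e-10, rtol = 1e-10)
      y <- o[2, -1]
      nv <- sqrt(sum(y[4:6]^2))
      if (i > burn) S <- S + log(nv)
      y[4:6] <- y[4:6] / nv
    }
    S / ((total - burn) * dt)
  })
}
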