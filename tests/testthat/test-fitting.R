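test_that("noiseless DBA/2J-style series refit to the generating parameters", {
  ds <- generate_dataset(dba2j_params(), observation_params(), times = 0:12, seed = 1)
  fit <- fit_decay(ds, fit_config(seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$params_hat$b, 0.3, tolerance = 1e-3)
  expect_equal(fit$params_hat$tau, 6.5, tolerance = 1e-3)
  expect_equal(fit$params_hat$d, 0.5, tolerance = 1e-3)
  expect_lt(fit$loss_value, 1e-6)
})

test_that("round-trip recovery holds across the parameter domain", {
  set.seed(17)
  cases <- list(
    decay_params(100, 0.15, 3, 0.3),
    decay_params(100, 0.45, 5.5, 0.7),
    decay_params(100, 0.25, 1.5, 0.9),
    decay_params(100, 0.6, 4, 0.1)
  )
  for (p in cases) {
    ds <- generate_dataset(p, observation_params(noise_floor_fraction = 0),
                           times = 0:12, seed = 3)
    fit <- fit_decay(ds)
    expect_equal(fit$params_hat$b, p$b, tolerance = 1e-3)
    expect_equal(fit$params_hat$tau, p$tau, tolerance = 1e-3)
    expect_equal(fit$params_hat$d, p$d, tolerance = 1e-3)
    # no multistart solution beats the truth on noiseless data
    truth_loss <- rgcprog:::fit_objective(
      c(p$b, p$tau, p$d),
      rgcprog:::prep_fit_data(ds, fit_config()), fit_config())
    expect_lte(truth_loss, min(fit$starts$refined_loss) + 1e-9)
  }
})

test_that("flat series recover the null model with a diagnostic", {
  ds <- generate_dataset(decay_params(100, 0, 2, 0.5), observation_params(),
                         times = 0:8, seed = 1)
  fit <- fit_decay(ds)
  expect_lte(fit$params_hat$b, 1e-6)
  expect_match(fit$diagnostics, "not identifiable", all = FALSE)
})

test_that("insufficient time points are rejected with an identifiability error", {
  ds <- generate_dataset(dba2j_params(), observation_params(), times = c(0, 6, 12))
  expect_error(fit_decay(ds), ">= 4 distinct")
})

test_that("noisy averaged series give calibrated bootstrap intervals", {
  # 5%-of-baseline noise, 32 replicate animals averaged per time point;
  # 100 seeded repetitions, 99 bootstrap draws per repetition: each
  # generating parameter should sit inside its 95% interval in >= 90%
  obs <- observation_params(function_noise_sd = 5, structure_noise_sd = 5)
  truth <- c(b = 0.3, tau = 6.5, d = 0.5)
  cover <- vapply(seq_len(100), function(s) {
    ds <- generate_dataset(dba2j_params(), obs, times = 2:12, replicates = 32,
                           seed = 2000 + s)
    ci <- bootstrap_ci(ds, fit_config(bootstrap_reps = 99, seed = 2000 + s))
    ci[, "lower"] <= truth & truth <= ci[, "upper"]
  }, logical(3))
  expect_gte(mean(cover["b", ]), 0.90)
  expect_gte(mean(cover["tau", ]), 0.90)
  expect_gte(mean(cover["d", ]), 0.90)
})

test_that("bootstrap intervals are seeded and collapse on noiseless data", {
  ds <- generate_dataset(dba2j_params(), observation_params(), times = 0:12, seed = 1)
  ci1 <- bootstrap_ci(ds, fit_config(bootstrap_reps = 25, seed = 5))
  ci2 <- bootstrap_ci(ds, fit_config(bootstrap_reps = 25, seed = 5))
  expect_identical(ci1, ci2)
  expect_lt(max(ci1[, "upper"] - ci1[, "lower"]), 1e-4)
  expect_error(bootstrap_ci(ds, fit_config(bootstrap_reps = 0)), ">= 1")
})

test_that("horizontal window matches independent root-finding", {
  # oracle: read both normalized curves at a deep loss level numerically
  win_oracle <- function(p, loss = 0.9999) {
    tgt <- 1 - loss
    tp <- uniroot(function(t) population_index(t, p) / p$H0 - tgt,
                  c(0, 500), tol = 1e-13)$root
    tf <- uniroot(function(t) function_index(t, p) / p$H0 - tgt,
                  c(0, 500), tol = 1e-13)$root
    tp - tf
  }
  p <- example_params()
  expect_equal(horizontal_window(p), 0.8253203, tolerance = 1e-6)
  expect_equal(horizontal_window(p), win_oracle(p), tolerance = 1e-4)
  d2 <- dba2j_params()
  expect_equal(horizontal_window(d2), 1.680138, tolerance = 1e-6)
  expect_equal(horizontal_window(d2), win_oracle(d2), tolerance = 1e-4)
  # the window shrinks with d and vanishes as d -> 1
  ds <- seq(0.1, 1, by = 0.1)
  wins <- sapply(ds, function(d) horizontal_window(decay_params(100, 0.3, 2, d)))
  expect_true(all(diff(wins) < 1e-12))
  expect_equal(wins[length(wins)], 0)
  expect_error(horizontal_window(decay_params(100, 0, 2, 0.5)), "b = 0")
})

test_that("horizontal window at a chosen loss level interpolates to the asymptote", {
  p <- example_params()
  # shallow loss reads near tau, deep loss near the asymptotic offset
  expect_equal(horizontal_window(p, loss_fraction = 1e-6), p$tau, tolerance = 1e-3)
  expect_equal(horizontal_window(p, loss_fraction = 0.9999),
               horizontal_window(p), tolerance = 1e-3)
  expect_error(horizontal_window(p, loss_fraction = 1.5), "\\(0, 1\\)")
  expect_equal(horizontal_window(decay_params(100, 0.3, 2, 1), 0.5), 0)
})

test_that("vertical gap equals the undisguised dysfunction of sick cells", {
  p <- example_params()
  expect_equal(vertical_gap(p, 1), 0.15)  # (1 - 0.5) * 30 / 100
  expect_equal(vertical_gap(decay_params(100, 0.3, 2, 1), c(0, 1, 5)), c(0, 0, 0))
  # algebraic identity (1-d) S(t) / H0, and the peak sits at t = tau
  for (p in random_params(10, seed = 3)) {
    t <- seq(0, 15, by = 0.1)
    expect_equal(vertical_gap(p, t), (1 - p$d) * sick_at(t, p) / p$H0,
                 tolerance = 1e-12)
    if (p$b > 0 && p$d < 1) {
      g <- vertical_gap(p, t)
      expect_lt(abs(t[which.max(g)] - min(p$tau, max(t))), 0.11)
      expect_true(all(g <= 1 - p$d + 1e-12))
    }
  }
  expect_error(vertical_gap(p, -1), "t must")
})

test_that("raw-scale fitting with profiled scales matches normalized fitting", {
  obs <- observation_params(function_scale = 2.2, structure_scale = 0.03,
                            noise_floor_fraction = 0)
  ds <- generate_dataset(dba2j_params(), obs, times = 0:12, seed = 1)
  fit_raw <- fit_decay(ds, fit_config(normalize = FALSE))
  expect_equal(fit_raw$params_hat$b, 0.3, tolerance = 1e-3)
  expect_equal(fit_raw$params_hat$tau, 6.5, tolerance = 1e-3)
  expect_equal(fit_raw$params_hat$d, 0.5, tolerance = 1e-3)
})
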