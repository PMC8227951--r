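test_that("three-state scheme encodes the decay parameters", {
  sch <- three_state_scheme(example_params())
  expect_equal(sch$stage_labels, c("Healthy", "Sick", "Dead"))
  expect_equal(sum(grepl("^Sick_", sch$state_labels)), 2L)  # tau/step = 2
  expect_equal(unname(sch$transition["Healthy", "Sick_1"]), 0.3)
  expect_equal(sch$function_coefficients, c(1, 0.5, 0))
  # per-step probability scales with step size: 1 - (1-b)^h
  sch_h <- three_state_scheme(example_params(), step_size = 0.5)
  expect_equal(unname(sch_h$transition["Healthy", "Sick_1"]), 1 - 0.7^0.5)
  # DBA/2J lag of 6.5 months at half-month steps -> 13 substates
  expect_equal(sum(grepl("^Sick_", three_state_scheme(dba2j_params(), 0.5)$state_labels)), 13L)
  # b = 0: healthy stage absorbing
  sch0 <- three_state_scheme(decay_params(100, 0, 2, 0.5))
  expect_equal(unname(sch0$transition["Healthy", "Healthy"]), 1)
})

test_that("incommensurate lag is rejected with a usable suggestion", {
  err <- tryCatch(three_state_scheme(dba2j_params(), step_size = 1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "not an integer multiple")
  expect_match(err, "0.5")  # suggested step divides both tau = 6.5 and 1
  expect_error(three_state_scheme(example_params(), step_size = 0.3),
               "must divide 1")
})

test_that("scheme constructor validates probability rows", {
  expect_error(
    stage_scheme(c("A", "B"), matrix(c(0.5, 0.4, 0, 1), 2, byrow = TRUE),
                 state_stage = c(1L, 2L), function_coefficients = c(1, 0),
                 structure_present = c(TRUE, FALSE)),
    "sum to 1")
})

test_that("expected-value propagation reproduces the closed forms exactly", {
  for (p in list(example_params(), dba2j_params(), decay_params(250, 0.15, 4, 0.8))) {
    step <- if (p$tau %% 1 == 0) 1 else 0.5
    sch <- three_state_scheme(p, step_size = step)
    horizon <- 14
    ex <- simulate_expected(sch, p$H0, horizon)
    tr <- trajectory(p, ex$time)
    expect_equal(ex$Healthy, tr$healthy, tolerance = 1e-9)
    expect_equal(ex$Sick, tr$sick, tolerance = 1e-9)
    expect_equal(ex$Dead, tr$dead, tolerance = 1e-9)
    # derived indices agree too
    idx <- stage_indices(ex)
    expect_equal(idx$function_index, tr$function_index, tolerance = 1e-9)
    expect_equal(idx$structure_index, tr$population_index, tolerance = 1e-9)
  }
})

test_that("expected propagation degenerate cases", {
  sch0 <- three_state_scheme(decay_params(100, 0, 2, 0.5))
  ex <- simulate_expected(sch0, 100, 10)
  expect_equal(ex$Healthy, rep(100, 11))
  ex0 <- simulate_expected(three_state_scheme(example_params()), 100, 0)
  expect_equal(nrow(ex0), 1L)
  expect_equal(ex0$Healthy, 100)
})

test_that("stochastic runs conserve cells, respect seeds, and track expectations", {
  sch <- three_state_scheme(example_params())
  a <- simulate_stochastic(sch, 1000, 6, seed = 11)
  b <- simulate_stochastic(sch, 1000, 6, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_stochastic(sch, 1000, 6, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
  # conservation in every replicate
  for (s in 1:5) {
    run <- simulate_stochastic(sch, 500, 8, seed = s)
    expect_true(all(run$Healthy + run$Sick + run$Dead == 500))
  }
  # large-N fraction sick at t = 1 near b = 0.3 (3 binomial SEs)
  big <- simulate_stochastic(sch, 1e5, 1, seed = 99)
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(big$Sick[2] / 1e5 - 0.3), 3 * se)
})

test_that("stochastic means converge to expected counts with population size", {
  sch <- three_state_scheme(example_params())
  ex <- simulate_expected(sch, 1, 5)  # per-cell expected occupancy
  for (n0 in c(1e2, 1e4, 1e6)) {
    run <- simulate_stochastic(sch, n0, 5, seed = 21)
    # each stage count within 4 SEs of its expectation at the horizon
    for (stage in c("Healthy", "Sick", "Dead")) {
      prop <- ex[[stage]][6]
      se <- sqrt(max(prop * (1 - prop), 1e-12) / n0)
      expect_lt(abs(run[[stage]][6] / n0 - prop), 4 * se + 1e-12)
    }
  }
  # mean over replicates at n0 = 1000 tracks expectation at every step
  sims <- sapply(1:200, function(s) simulate_stochastic(sch, 1000, 5, seed = 300 + s)$Sick)
  exp_sick <- simulate_expected(sch, 1000, 5)$Sick
  mc_se <- apply(sims, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(sims) - exp_sick) <= 4 * mc_se + 1e-9))
})

test_that("every dying cell spends exactly tau sick under deterministic residence", {
  sch <- three_state_scheme(example_params())
  ev <- simulate_cells(sch, 300, 30, seed = 5)
  wide <- reshape(ev, idvar = "cell", timevar = "stage", direction = "wide")
  res <- wide$entry_time.Dead - wide$entry_time.Sick
  res <- res[!is.na(res)]
  expect_gt(length(res), 0)
  expect_true(all(res == 2))
  # geometric residence variant: mean near tau but not constant
  schg <- three_state_scheme(example_params(), residence = "geometric")
  evg <- simulate_cells(schg, 2000, 60, seed = 5)
  wg <- reshape(evg, idvar = "cell", timevar = "stage", direction = "wide")
  rg <- wg$entry_time.Dead - wg$entry_time.Sick
  rg <- rg[!is.na(rg)]
  expect_gt(length(unique(rg)), 1L)
  expect_equal(mean(rg), 2, tolerance = 0.15)
})

test_that("seven-stage scheme validates its configuration", {
  sch <- seven_stage_scheme()
  expect_equal(length(sch$stage_labels), 7L)
  expect_true(all(diff(sch$function_coefficients) <= 0))
  expect_equal(sch$function_coefficients[1], 1)
  expect_equal(sch$function_coefficients[6:7], c(0, 0))
  expect_true(all(sch$structure_present[1:4]))
  expect_false(any(sch$structure_present[5:7]))
  expect_error(seven_stage_scheme(progression = rep(1.2, 6)), "probabilities")
  expect_error(seven_stage_scheme(function_coefficients = c(1, 0.2, 0.5, 0.2, 0, 0, 0)),
               "non-increasing")
  expect_error(seven_stage_scheme(function_coefficients = c(1, 1, 1, 1, 1, 0.5, 0.2)),
               "function coefficient 0")
  # zero transition probabilities freeze the population
  frozen <- simulate_expected(seven_stage_scheme(progression = rep(0, 6)), 100, 5)
  expect_equal(frozen$Healthy, rep(100, 6))
})

test_that("a collapsed seven-stage chain reproduces the three-state model", {
  # stages 1-3 act as a 3-step sick chain (coefficient d), 4-6 as dead:
  # equivalent to the three-state scheme with tau = 3 on expected counts
  p <- decay_params(100, 0.3, 3, 0.5)
  seven <- seven_stage_scheme(progression = c(0.3, 1, 1, 1, 1, 1),
                              function_coefficients = c(1, 0.5, 0.5, 0.5, 0, 0, 0),
                              structure_present = c(rep(TRUE, 4), rep(FALSE, 3)))
  ex7 <- simulate_expected(seven, 100, 12)
  ex3 <- simulate_expected(three_state_scheme(p), 100, 12)
  sick7 <- ex7[["At Risk"]] + ex7$Sick + ex7[["Very sick"]]
  dead7 <- ex7$Dying + ex7$Dead + ex7$Effaced
  expect_equal(ex7$Healthy, ex3$Healthy, tolerance = 1e-12)
  expect_equal(sick7, ex3$Sick, tolerance = 1e-12)
  expect_equal(dead7, ex3$Dead, tolerance = 1e-12)
})
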