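# Sampled valid parameter sets for property-style tests.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    decay_params(H0 = runif(1, 50, 2000),
                 b = runif(1, 0.02, 0.7),
                 tau = runif(1, 0, 8),
                 d = runif(1, 0, 1))
  })
}

# Contrast fixture that is exactly affine in log10 contrast; shifted up if
# needed so amplitudes stay non-negative (shift changes intercept, not slope).
affine_contrast_series <- function(intercept, slope,
                                   contrasts = c(0.05, 0.1, 0.2, 0.4, 0.8, 1)) {
  amp <- intercept + slope * log10(contrasts)
  if (min(amp) < 0) amp <- amp - min(amp)
  contrast_series(contrasts, amp)
}

expect_conservation <- function(traj, H0, tol = 1e-9) {
  expect_lt(max(abs(traj$healthy + traj$sick + traj$dead - H0)), tol * H0)
}
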