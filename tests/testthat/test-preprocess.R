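make_rec <- function(m, fs = 500) emg_recording(m, fs = fs)

test_that("rectification is elementwise absolute value and idempotent", {
  r <- make_rec(matrix(c(-1, 2, -3, 0, 4, -5), 3, 2))
  expect_equal(rectify(r)$samples, matrix(c(1, 2, 3, 0, 4, 5), 3, 2))
  expect_identical(rectify(rectify(r)), rectify(r))
  nonneg <- make_rec(matrix(1:6, 3, 2))
  expect_equal(rectify(nonneg)$samples, nonneg$samples)
})

test_that("IEMG filter matches its closed-form step response and DC gain", {
  fs <- 500
  spec <- iemg_filter()
  step <- make_rec(matrix(1, 5000, 1), fs = fs)
  out <- envelope_filter(step, spec)$samples
  ## closed form of the discretized difference-of-exponentials step response
  n <- nrow(out)
  a1 <- exp(-spec$rate_slow / fs); a2 <- exp(-spec$rate_fast / fs)
  expected_final <- spec$gain / fs * ((1 - a1^n) / (1 - a1) - (1 - a2^n) / (1 - a2))
  expect_equal(out[n, 1], expected_final, tolerance = 1e-12)
  expect_equal(out[n, 1], iemg_dc_gain(spec, fs), tolerance = 1e-6)
  ## zero in, zero out; nonnegativity conserved for rectified input
  zero <- make_rec(matrix(0, 100, 3), fs = fs)
  expect_true(all(envelope_filter(zero, spec)$samples == 0))
  set.seed(1)
  noise <- make_rec(abs(matrix(rnorm(2000 * 2), 2000, 2)), fs = fs)
  filtered <- envelope_filter(noise, spec)
  expect_true(all(filtered$samples >= 0))
  expect_lt(var(filtered$samples[, 1]), var(noise$samples[, 1]))
})

test_that("IEMG filter attenuates content above 10 Hz by over 20 dB", {
  fs <- 500
  spec <- iemg_filter()
  a <- spec$rate_slow; b <- spec$rate_fast
  gain_at <- function(f) {
    w <- 2 * pi * f
    spec$gain * Mod(1 / complex(real = a, imaginary = w) -
                      1 / complex(real = b, imaginary = w))
  }
  expect_lt(20 * log10(gain_at(10) / gain_at(0)), -20)
  ## empirical check on a 10 Hz sinusoid riding on a pedestal
  t <- seq(0, 4, by = 1 / fs)
  x <- make_rec(matrix(1 + sin(2 * pi * 10 * t), ncol = 1), fs = fs)
  y <- envelope_filter(x, spec)$samples[-(1:fs), 1]   # drop transient
  ripple_in <- 1                                      # input amplitude at 10 Hz
  ripple_out <- (max(y) - min(y)) / 2 / iemg_dc_gain(spec, fs)
  expect_lt(20 * log10(ripple_out / ripple_in), -20)
})

test_that("unstable or malformed filter specifications are rejected", {
  expect_error(iemg_filter(rate_slow = -1), class = "fpcnn_config_error")
  expect_error(iemg_filter(rate_slow = 20, rate_fast = 10),
               class = "fpcnn_config_error")
})

test_that("unit normalization scales by source extrema and never clips", {
  r <- make_rec(matrix(c(2, 4, 6), 3, 1))
  expect_equal(normalize_unit(r)$samples, matrix(c(0, 0.5, 1), 3, 1))
  scaled <- make_rec(matrix(c(0, 0.25, 1), 3, 1))
  expect_equal(normalize_unit(scaled)$samples, scaled$samples)
  ## self-normalization is idempotent
  once <- normalize_unit(r)
  expect_equal(normalize_unit(once)$samples, once$samples)
  ## new-day data normalized with stored stats may leave [0, 1]; no clipping
  old_stats <- compute_norm_stats(r)
  new_day <- make_rec(matrix(c(1, 8), 2, 1))
  out <- normalize_unit(new_day, old_stats)$samples
  expect_equal(out, matrix(c(-0.25, 1.5), 2, 1))
  ## constant channel maps to zero with a warning
  const <- make_rec(matrix(c(3, 3, 3, 1, 2, 3), 3, 2))
  expect_warning(z <- normalize_unit(const), "constant")
  expect_equal(z$samples[, 1], rep(0, 3))
  expect_equal(z$samples[, 2], c(0, 0.5, 1))
})

test_that("rate conversion gives exact lengths and preserves band-limited shape", {
  fs_in <- 500
  r <- make_rec(matrix(rep(2.5, 5000), ncol = 1), fs = fs_in)
  out <- resample_to_angle_rate(r, 120)
  expect_equal(nrow(out$samples), 1200)       # 5000 * 120 / 500
  expect_equal(out$fs, 120)
  expect_true(all(out$samples == 2.5))        # constants preserved exactly
  ## a slow sinusoid (well under the 60 Hz target Nyquist) is reproduced
  t_in <- seq(0, 4999) / fs_in
  x <- make_rec(matrix(sin(2 * pi * 2 * t_in), ncol = 1), fs = fs_in)
  y <- resample_to_angle_rate(x, 120)$samples[, 1]
  ideal <- sin(2 * pi * 2 * seq(0, 1199) / 120)
  expect_gt(cor(y, ideal), 0.99)
  expect_lt(max(abs(y - ideal)), 1e-3)
  expect_error(resample_to_angle_rate(r, 0), class = "fpcnn_config_error")
  expect_error(resample_to_angle_rate(r, 600), class = "fpcnn_config_error")
})

test_that("the full chain preserves channel count, ids and nonnegativity", {
  sess <- small_session()
  raw <- sess$trials[[1]]$emg
  env <- preprocess_trial(raw)
  expect_s3_class(env, "envelope_signal")
  expect_equal(ncol(env$samples), 32)
  expect_identical(env$channel_ids, raw$channel_ids)
  expect_equal(env$fs, 120)
  expect_true(all(env$samples >= 0))
  expect_true(all(env$samples <= 1 + 1e-12))  # self-stats map into [0, 1]
  ## session-level preprocessing pools stats across trials
  prep <- preprocess_session(sess)
  expect_length(prep$trials, 5)
  expect_s3_class(prep$stats, "norm_stats")
  pooled <- sapply(prep$trials, function(tr) max(tr$env$samples))
  expect_true(all(pooled <= 1 + 1e-12))
  # the session-wide max reaches 1 (up to resampling interpolation)
  expect_equal(max(pooled), 1, tolerance = 1e-3)
})
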