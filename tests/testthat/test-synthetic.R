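test_that("paradigm angle traces follow the sign convention per joint", {
  ang <- build_paradigm_angles(paradigm_spec())$angles
  ## WF excursions positive and WE negative, on joint 1 only
  expect_gt(max(ang[, "WFWE"]), 0)
  expect_lt(min(ang[, "WFWE"]), 0)
  expect_gt(max(ang[, "PS"]), 0)
  expect_lt(min(ang[, "PS"]), 0)
  expect_gt(max(ang[, "HGHO"]), 0)
  expect_lt(min(ang[, "HGHO"]), 0)
  ## a WF-only paradigm moves joint 1 positively and leaves joints 2-3 at rest
  wf <- build_paradigm_angles(paradigm_spec(motion_order = "WF"))$angles
  expect_gte(min(wf[, "WFWE"]), 0)
  expect_gt(max(wf[, "WFWE"]), 0)
  expect_equal(wf[, "PS"], rep(0, nrow(wf)))
  expect_equal(wf[, "HGHO"], rep(0, nrow(wf)))
  ## every excursion starts and ends at the central position
  expect_equal(ang[1, ], c(WFWE = 0, PS = 0, HGHO = 0))
  expect_equal(ang[nrow(ang), ], c(WFWE = 0, PS = 0, HGHO = 0))
})

test_that("zero peak angles give an all-zero trace and durations give exact lengths", {
  zero <- paradigm_spec(peak_angle = c(WF = 0, WE = 0, P = 0, S = 0,
                                       HG = 0, HO = 0))
  expect_true(all(build_paradigm_angles(zero)$angles == 0))
  ## 2 motions x (2 s hold + 2 s rest) + leading 2 s rest = 10 s -> 1200 samples
  sp <- paradigm_spec(motion_order = c("WF", "WE"), hold_duration = 2,
                      rest_duration = 2)
  expect_equal(nrow(build_paradigm_angles(sp)$angles), 10 * 120)
  ## default paradigm: 1 + 12 * 3 = 37 s at 120 Hz
  expect_equal(nrow(build_paradigm_angles(paradigm_spec())$angles), 37 * 120)
})

test_that("invalid paradigm specifications are rejected", {
  expect_error(paradigm_spec(hold_duration = 0), class = "fpcnn_config_error")
  expect_error(paradigm_spec(motion_order = "XX"), class = "fpcnn_config_error")
  expect_error(paradigm_spec(peak_angle = c(WF = -10, WE = -60, P = 70,
                                            S = -70, HG = 50, HO = -50)),
               class = "fpcnn_config_error")
})

test_that("activations rectify excursions per primitive and vanish at rest", {
  expect_true(all(simulate_activations(matrix(0, 50, 3)) == 0))
  wf <- build_paradigm_angles(paradigm_spec(motion_order = "WF"))
  act <- simulate_activations(wf)
  expect_gt(max(act[, "WF"]), 0.99)
  expect_true(all(act[, c("WE", "P", "S", "HG", "HO")] == 0))
  ## peak activation coincides with peak angle (memoryless mapping)
  expect_equal(which.max(act[, "WF"]), which.max(wf$angles[, "WFWE"]))
  ## nonnegative and unit-peak by construction
  full <- simulate_activations(build_paradigm_angles(paradigm_spec()))
  expect_true(all(full >= 0))
  expect_equal(unname(apply(full, 2, max)), rep(1, 6))
})

test_that("synthetic EMG is carrier noise modulated by the planted mixture", {
  sp <- small_paradigm()
  ang <- build_paradigm_angles(sp)
  act <- simulate_activations(ang)
  syn <- synergy_spec()
  emg <- synthesize_emg(act, syn, seed = 5)
  expect_equal(dim(emg$samples), c(round(nrow(act) * 500 / 120), 32))
  ## envelope (rectified + lowpassed) tracks the known modulator on
  ## active channels
  env <- envelope_filter(rectify(emg))
  t_in <- seq(0, nrow(act) - 1) / 120
  t_out <- seq(0, nrow(emg$samples) - 1) / 500
  modulator <- apply(act %*% t(syn$mixing_matrix) + syn$noise_floor, 2,
                     function(col) approx(t_in, col, xout = t_out, rule = 2)$y)
  active <- which(apply(syn$mixing_matrix, 1, max) >= 1)
  for (ch in active) {
    expect_gt(cor(env$samples[, ch], modulator[, ch]), 0.8)
  }
  ## a channel with a zero mixing row carries only the noise floor
  m0 <- syn$mixing_matrix
  m0[32, ] <- 0
  syn0 <- synergy_spec(mixing_matrix = m0, noise_floor = 0.5)
  emg0 <- synthesize_emg(act, syn0, seed = 5)
  expect_lt(max(abs(emg0$samples[, 32])) / 0.5, 6)  # bounded by carrier tails
  expect_equal(stats::sd(emg0$samples[, 32]), 0.5, tolerance = 0.05)
})

test_that("zero activations with zero noise floor give silence; Nyquist violations error", {
  act <- matrix(0, 120, 6)
  syn <- synergy_spec(noise_floor = 0)
  expect_true(all(synthesize_emg(act, syn, seed = 1)$samples == 0))
  bad <- synergy_spec(carrier_band = c(20, 260))
  expect_error(synthesize_emg(act, bad, fs_emg = 500, seed = 1),
               class = "fpcnn_config_error")
  expect_error(synthesize_emg(act - 1, syn), class = "fpcnn_config_error")
})

test_that("day shift: identity is a no-op, gains scale exactly, rotation permutes", {
  sess <- small_session()
  ident <- apply_day_shift(sess, day_shift_spec())
  for (i in seq_along(sess$trials)) {
    expect_identical(ident$trials[[i]]$emg$samples, sess$trials[[i]]$emg$samples)
    expect_identical(ident$trials[[i]]$angles, sess$trials[[i]]$angles)
  }
  gains <- rep(1, 32); gains[1] <- 2
  doubled <- apply_day_shift(sess, day_shift_spec(channel_gain = gains))
  expect_equal(doubled$trials[[1]]$emg$samples[, 1],
               2 * sess$trials[[1]]$emg$samples[, 1])
  expect_equal(doubled$trials[[1]]$emg$samples[, 2],
               sess$trials[[1]]$emg$samples[, 2])
  rot <- apply_day_shift(sess, day_shift_spec(layout_shift = 1))
  src <- fpcnn:::shift_permutation(1)
  expect_equal(unname(rot$trials[[1]]$emg$samples),
               unname(sess$trials[[1]]$emg$samples[, src]))
})

test_that("sessions are deterministic in the seed with the stated trial counts", {
  sp <- small_paradigm()
  a <- generate_session(paradigm = sp, n_trials = 2, seed = 3)
  b <- generate_session(paradigm = sp, n_trials = 2, seed = 3)
  expect_identical(a$trials[[1]]$emg$samples, b$trials[[1]]$emg$samples)
  expect_identical(a$trials[[2]]$angles$angles, b$trials[[2]]$angles$angles)
  c <- generate_session(paradigm = sp, n_trials = 2, seed = 4)
  expect_false(identical(a$trials[[1]]$emg$samples, c$trials[[1]]$emg$samples))
  ## trials within a session are independent noise realizations
  expect_false(identical(a$trials[[1]]$emg$samples, a$trials[[2]]$emg$samples))
  expect_equal(length(generate_session(paradigm = sp, n_trials = 5,
                                       seed = 1)$trials), 5)
  expect_error(generate_session(paradigm = sp, n_trials = 0),
               class = "fpcnn_config_error")
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(generate_session(paradigm = small_paradigm(), n_trials = 1, seed = 9))
  expect_identical(.Random.seed, before)
})
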