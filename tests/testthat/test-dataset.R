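sync_pair <- function(n_env, n_ang, fs = 120) {
  synchronize(emg_recording(matrix(1, n_env, 32), fs = fs),
              angle_recording(matrix(0, n_ang, 3), fs = fs))
}

test_that("synchronization truncates to the common length within tolerance", {
  expect_equal(nrow(sync_pair(1200, 1200)$env), 1200)
  s <- sync_pair(1200, 1195)
  expect_equal(nrow(s$env), 1195)
  expect_equal(nrow(s$angles), 1195)
  ## 300-sample (2.5 s) mismatch is a recording fault
  expect_error(sync_pair(1200, 900), class = "fpcnn_data_error")
  expect_error(synchronize(emg_recording(matrix(1, 10, 32), fs = 120),
                           angle_recording(matrix(0, 10, 3), fs = 60)),
               class = "fpcnn_data_error")
})

test_that("window segmentation follows the count formula and mean targets", {
  trial <- function(n) list(env = matrix(runif(n * 32), n, 32),
                            angles = matrix(10, n, 3,
                                            dimnames = list(NULL, c("WFWE", "PS", "HGHO"))),
                            fs = 120)
  sw <- segment_windows(trial(660))
  expect_equal(dim(sw$X), c(51, 60, 32))       # floor((660 - 60) / 12) + 1
  ## boundary: a trial of exactly one window
  sw1 <- segment_windows(trial(60))
  expect_equal(dim(sw1$X)[1], 1)
  expect_equal(sw1$start, 1L)
  ## constant angles give constant mean targets
  expect_equal(unname(sw$y), matrix(10, 51, 3))
  ## too-short trial: zero windows with a warning
  expect_warning(sw0 <- segment_windows(trial(59)), "shorter")
  expect_equal(dim(sw0$X)[1], 0)
})

test_that("window counts agree with a brute-force enumerator on random lengths", {
  set.seed(7)
  for (n in sample(60:1500, 25)) {
    tr <- list(env = matrix(0, n, 32), angles = matrix(0, n, 3), fs = 120)
    got <- dim(segment_windows(tr)$X)[1]
    ## oracle: enumerate admissible starts directly
    starts <- 0
    s <- 1
    while (s + 60 - 1 <= n) { starts <- starts + 1; s <- s + 12 }
    expect_equal(got, starts)
  }
})

test_that("window contents are contiguous in-trial slices with mean-angle targets", {
  ds <- small_dataset()
  sess <- small_session()
  prep <- preprocess_session(sess)
  tr1 <- synchronize(prep$trials[[1]]$env, prep$trials[[1]]$angles)
  i <- which(ds$trial == 1)[3]
  s <- ds$start[i]
  expect_equal(ds$X[i, , ], tr1$env[s:(s + 59), ], ignore_attr = TRUE)
  expect_equal(unname(ds$y[i, ]), unname(colMeans(tr1$angles[s:(s + 59), ])))
})

test_that("fold construction matches both experiment designs", {
  f10 <- make_folds(1:10, mode = "initial", seed = 1)
  sizes <- table(f10$group_of_trial)
  expect_equal(unname(sort(as.integer(sizes))), rep(2, 5))
  expect_setequal(names(f10$group_of_trial), as.character(1:10))
  ## second design: one trial per group, in order
  f5 <- make_folds(1:5, mode = "second")
  expect_equal(unname(f5$group_of_trial), 1:5)
  ## determinism and reshuffling
  expect_identical(make_folds(1:10, mode = "initial", seed = 1), f10)
  expect_false(identical(f10$group_of_trial,
                         make_folds(1:10, mode = "initial", seed = 2)$group_of_trial))
  ## wrong trial counts
  expect_error(make_folds(1:4, mode = "initial"), class = "fpcnn_config_error")
  expect_error(make_folds(1:6, mode = "second"), class = "fpcnn_config_error")
})

test_that("fold test sets partition the trials (no overlap, full coverage)", {
  f <- make_folds(1:10, mode = "initial", seed = 3)
  test_sets <- lapply(1:5, function(g) fold_test_trials(f, g))
  expect_setequal(unlist(test_sets), 1:10)
  expect_equal(length(unlist(test_sets)), 10)   # pairwise disjoint
})
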