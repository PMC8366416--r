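## Windowed supervised dataset construction and trial-wise fold design.
##
## A sample is one 500 ms envelope window (60 rows at 120 Hz x 32
## channels) paired with the mean of each joint angle over the window.
## Windows slide in 100 ms (12-sample) steps and never cross trial
## boundaries; cross-validation folds are unions of whole trials so no
## window leaks between training and testing.

#' Synchronize an envelope stream with an angle stream
#'
#' Both streams must share the sampling rate; they are truncated to the
#' shorter length.  A mismatch above `max_mismatch_s` seconds indicates a
#' recording fault and raises an error.
#'
#' @param env An `emg_recording` at the angle rate (envelope stage).
#' @param angles An `angle_recording` at the same rate.
#' @param max_mismatch_s Largest tolerated length difference in seconds.
#' @return List with matrices `env` (T x 32) and `angles` (T x 3) of
#'   equal row count, plus `fs`.
#' @export
synchronize <- function(env, angles, max_mismatch_s = 1) {
  e <- if (inherits(env, "emg_recording")) env$samples else env
  a <- if (inherits(angles, "angle_recording")) angles$angles else angles
  fs_e <- if (inherits(env, "emg_recording")) env$fs else NA
  fs_a <- if (inherits(angles, "angle_recording")) angles$fs else fs_e
  if (!is.na(fs_e) && !is.na(fs_a) && fs_e != fs_a)
    stop_data("sampling rates differ: ", fs_e, " vs ", fs_a, " Hz")
  fs <- if (!is.na(fs_a)) fs_a else 120
  mismatch <- abs(nrow(e) - nrow(a))
  if (mismatch > max_mismatch_s * fs)
    stop_data("stream length mismatch of ", mismatch, " samples (",
              round(mismatch / fs, 2), " s) exceeds ", max_mismatch_s, " s")
  n <- min(nrow(e), nrow(a))
  list(env = e[seq_len(n), , drop = FALSE],
       angles = a[seq_len(n), , drop = FALSE], fs = fs)
}

#' Segment a synchronized trial into overlapping windows
#'
#' Window and stride lengths are converted to samples by rounding
#' (500 ms -> 60 samples and 100 ms -> 12 samples at 120 Hz, i.e. 400 ms
#' overlap).  The target of each window is the per-joint mean angle over
#' its 60 samples.  A trial shorter than one window yields zero windows
#' with a warning.
#'
#' @param trial A list from [synchronize()] (fields `env`, `angles`, `fs`).
#' @param win_ms Window length in milliseconds.
#' @param stride_ms Hop between window starts in milliseconds.
#' @return List with `X` (n x win x channels array), `y` (n x 3 matrix),
#'   and `start` (1-based window start indices).
#' @export
segment_windows <- function(trial, win_ms = 500, stride_ms = 100) {
  env <- trial$env; ang <- trial$angles; fs <- trial$fs
  stopifnot(nrow(env) == nrow(ang))
  win <- round(win_ms * fs / 1000)
  stride <- round(stride_ms * fs / 1000)
  n_t <- nrow(env)
  if (n_t < win) {
    warning("trial of ", n_t, " samples is shorter than one ", win,
            "-sample window; no windows produced")
    return(list(X = array(0, c(0, win, ncol(env))),
                y = matrix(0, 0, ncol(ang)), start = integer(0)))
  }
  starts <- seq(1L, n_t - win + 1L, by = stride)
  n <- length(starts)
  X <- array(0, c(n, win, ncol(env)))
  y <- matrix(0, n, ncol(ang), dimnames = list(NULL, colnames(ang)))
  for (i in seq_len(n)) {
    idx <- starts[i]:(starts[i] + win - 1L)
    X[i, , ] <- env[idx, ]
    y[i, ] <- colMeans(ang[idx, , drop = FALSE])
  }
  list(X = X, y = y, start = starts)
}

#' Build the windowed dataset for a whole session
#'
#' Runs [preprocess_session()], synchronizes each trial, segments it, and
#' stacks the windows of all trials.
#'
#' @param session An `emg_session`.
#' @param filter An [iemg_filter()].
#' @param stats Optional stored `norm_stats` (new-day direct testing);
#'   `NULL` pools statistics over this session.
#' @param win_ms,stride_ms Window geometry in milliseconds.
#' @param fs_out Envelope/angle rate in Hz.
#' @return An object of class `emg_dataset`: list with `X`
#'   (n x 60 x 32 array), `y` (n x 3 matrix, degrees), `trial` (integer
#'   provenance vector), `start` (window start indices), `stats`, `fs`.
#' @export
build_dataset <- function(session, filter = iemg_filter(), stats = NULL,
                          win_ms = 500, stride_ms = 100, fs_out = 120) {
  prep <- preprocess_session(session, filter = filter, stats = stats,
                             fs_out = fs_out)
  parts <- lapply(seq_along(prep$trials), function(i) {
    tr <- prep$trials[[i]]
    sw <- segment_windows(synchronize(tr$env, tr$angles), win_ms, stride_ms)
    sw$trial <- rep(i, nrow(sw$y))
    sw
  })
  X <- do.call(abind_first, lapply(parts, `[[`, "X"))
  structure(list(X = X,
                 y = do.call(rbind, lapply(parts, `[[`, "y")),
                 trial = unlist(lapply(parts, `[[`, "trial")),
                 start = unlist(lapply(parts, `[[`, "start")),
                 stats = prep$stats, fs = fs_out),
            class = "emg_dataset")
}

## rbind for 3-d arrays along the first axis.
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("<emg_dataset> %d windows of %d x %d from %d trials @ %g Hz\n",
              dim(x$X)[1], dim(x$X)[2], dim(x$X)[3],
              length(unique(x$trial)), x$fs))
  invisible(x)
}

#' Subset a dataset by trial membership
#'
#' @param dataset An `emg_dataset`.
#' @param trials Integer trial ids to keep.
#' @return The reduced `emg_dataset`.
#' @export
subset_trials <- function(dataset, trials) {
  keep <- dataset$trial %in% trials
  dataset$X <- dataset$X[keep, , , drop = FALSE]
  dataset$y <- dataset$y[keep, , drop = FALSE]
  dataset$trial <- dataset$trial[keep]
  dataset$start <- dataset$start[keep]
  dataset
}

#' Trial-wise five-fold assignment
#'
#' `initial` mode randomly partitions the trials into `k` groups of (as
#' near as possible) equal size — 10 trials into 5 pairs in the standard
#' design.  `second` mode requires exactly `k` trials and makes each
#' trial its own group, the reduced new-day design.
#'
#' @param trial_ids Integer vector of trial identifiers.
#' @param k Number of folds.
#' @param mode `"initial"` (random equal groups) or `"second"`
#'   (one trial per group).
#' @param seed Integer seed for the random partition.
#' @return An object of class `fold_split`: list with `k`,
#'   `group_of_trial` (named integer vector, groups 1..k), `mode`, `seed`.
#' @export
make_folds <- function(trial_ids, k = 5, mode = c("initial", "second"),
                       seed = 1L) {
  mode <- match.arg(mode)
  n <- length(trial_ids)
  if (anyDuplicated(trial_ids)) stop_config("trial_ids must be unique")
  if (mode == "initial" && n < k)
    stop_config("initial mode needs at least ", k, " trials, got ", n)
  if (mode == "second" && n != k)
    stop_config("second mode needs exactly ", k, " trials, got ", n)
  grp <- if (mode == "second") seq_len(k)
         else with_seed(seed, sample(rep_len(seq_len(k), n)))
  names(grp) <- as.character(trial_ids)
  structure(list(k = k, group_of_trial = grp, mode = mode, seed = seed),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  sizes <- table(x$group_of_trial)
  cat(sprintf("<fold_split> %d-fold (%s mode), group sizes: %s\n",
              x$k, x$mode, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Trials belonging to the test group of one fold
#'
#' @param folds A `fold_split`.
#' @param fold Fold index in 1..k.
#' @return Integer trial ids held out in that fold.
#' @export
fold_test_trials <- function(folds, fold) {
  as.integer(names(folds$group_of_trial)[folds$group_of_trial == fold])
}
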