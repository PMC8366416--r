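## Raw EMG -> normalized envelope chain: rectify, integrated-EMG (IEMG)
## low-pass, per-channel unit normalization, resample to the kinematic
## rate.  All stages are causal and per-channel; the pipeline order is
## fixed (rectify -> filter -> normalize -> resample).

#' Full-wave rectification
#'
#' @param rec An `emg_recording`.
#' @return The recording with `samples` replaced by their absolute value.
#' @export
rectify <- function(rec) {
  if (!inherits(rec, "emg_recording")) stop_data("rec must be an emg_recording")
  rec$samples <- abs(rec$samples)
  rec
}

#' IEMG envelope filter specification
#'
#' A causal second-order low-pass with impulse response
#' `h(t) = gain * (exp(-rate_slow * t) - exp(-rate_fast * t))`, the
#' difference-of-exponentials form classically used to turn rectified EMG
#' into a muscle-activation ("quasi-tension") envelope.  The defaults
#' (gain 6.44, rates 10.80 and 16.52 per second) are the published
#' coefficients of that filter family and are configuration defaults, not
#' quantities estimated here.
#'
#' @param gain Output gain `A`.
#' @param rate_slow,rate_fast Decay rates in 1/s; both must be positive
#'   and distinct (`rate_fast > rate_slow`).
#' @return An object of class `iemg_filter`.
#' @export
iemg_filter <- function(gain = 6.44, rate_slow = 10.80, rate_fast = 16.52) {
  if (rate_slow <= 0 || rate_fast <= 0)
    stop_config("filter rates must be positive (stability)")
  if (rate_fast <= rate_slow)
    stop_config("rate_fast must exceed rate_slow")
  if (!is.finite(gain * (1 / rate_slow - 1 / rate_fast)))
    stop_config("filter DC gain must be finite")
  structure(list(gain = gain, rate_slow = rate_slow, rate_fast = rate_fast),
            class = "iemg_filter")
}

#' DC gain of the discretized IEMG filter
#'
#' Steady-state output for a unit step input at sampling rate `fs`.
#'
#' @param spec An [iemg_filter()].
#' @param fs Sampling rate in Hz.
#' @export
iemg_dc_gain <- function(spec, fs) {
  spec$gain / fs * (1 / (1 - exp(-spec$rate_slow / fs)) -
                      1 / (1 - exp(-spec$rate_fast / fs)))
}

#' Apply the IEMG envelope filter
#'
#' Realized as the difference of two first-order recursive exponential
#' smoothers, so the filter is causal and the output of a nonnegative
#' (rectified) input stays nonnegative.
#'
#' @param rec A rectified `emg_recording`.
#' @param spec An [iemg_filter()].
#' @return The filtered recording (same rate, same channels).
#' @export
envelope_filter <- function(rec, spec = iemg_filter()) {
  if (!inherits(rec, "emg_recording")) stop_data("rec must be an emg_recording")
  if (!inherits(spec, "iemg_filter")) stop_config("spec must be an iemg_filter")
  a1 <- exp(-spec$rate_slow / rec$fs)
  a2 <- exp(-spec$rate_fast / rec$fs)
  s1 <- stats::filter(rec$samples, a1, method = "recursive")
  s2 <- stats::filter(rec$samples, a2, method = "recursive")
  out <- spec$gain / rec$fs * (as.matrix(s1) - as.matrix(s2))
  dimnames(out) <- dimnames(rec$samples)
  rec$samples <- out
  rec
}

#' Per-channel min-max normalization statistics
#'
#' @param rec An `emg_recording`, or a list of them whose per-channel
#'   minima/maxima are pooled (e.g. all trials of a training session).
#' @return An object of class `norm_stats`: list with `min` and `max`
#'   per-channel vectors.
#' @export
compute_norm_stats <- function(rec) {
  recs <- if (inherits(rec, "emg_recording")) list(rec) else rec
  mins <- do.call(pmin, lapply(recs, function(r) apply(r$samples, 2, min)))
  maxs <- do.call(pmax, lapply(recs, function(r) apply(r$samples, 2, max)))
  structure(list(min = mins, max = maxs), class = "norm_stats")
}

#' Scale each channel to the unit interval
#'
#' Per-channel min-max scaling `(x - min) / (max - min)` using statistics
#' taken from `stats_source` (default: the recording itself).  Data from
#' the source recording therefore lands in \[0, 1\]; data normalized with
#' *stored* statistics — e.g. a new day's recording scaled with the
#' training day's extrema — may fall outside that range and is
#' deliberately not clipped.  Constant channels map to 0 with a warning.
#'
#' @param rec An `emg_recording` (envelope stage).
#' @param stats_source A `norm_stats` object, an `emg_recording`, or
#'   `NULL` to use `rec` itself.
#' @return An `envelope_signal` (an `emg_recording` carrying the
#'   `norm_stats` used in field `normalization_stats`).
#' @export
normalize_unit <- function(rec, stats_source = NULL) {
  if (!inherits(rec, "emg_recording")) stop_data("rec must be an emg_recording")
  st <- if (is.null(stats_source)) compute_norm_stats(rec)
        else if (inherits(stats_source, "norm_stats")) stats_source
        else compute_norm_stats(stats_source)
  rng <- st$max - st$min
  flat <- rng <= 0
  if (any(flat)) {
    warning("constant channel(s) mapped to 0: ",
            paste(which(flat), collapse = ", "))
    rng[flat] <- 1
  }
  x <- sweep(sweep(rec$samples, 2, st$min, `-`), 2, rng, `/`)
  x[, flat] <- 0
  rec$samples <- x
  rec$normalization_stats <- st
  class(rec) <- c("envelope_signal", class(rec))
  rec
}

#' Resample an envelope recording to the joint-angle rate
#'
#' Rational-rate conversion (500 -> 120 Hz by default) by linear
#' interpolation onto the target time grid.  The IEMG stage has already
#' confined the signal far below the target Nyquist frequency, so
#' interpolation is alias-free here, preserves constants exactly, and
#' yields exactly `round(n * fs_out / fs_in)` output samples.
#'
#' @param rec An `emg_recording` (envelope stage).
#' @param fs_out Target rate in Hz; must be positive and below `rec$fs`.
#' @return The recording resampled to `fs_out`.
#' @export
resample_to_angle_rate <- function(rec, fs_out = 120) {
  if (!inherits(rec, "emg_recording")) stop_data("rec must be an emg_recording")
  if (fs_out <= 0) stop_config("fs_out must be positive")
  if (fs_out >= rec$fs) stop_config("fs_out must be below the input rate")
  n_in <- nrow(rec$samples)
  n_out <- round(n_in * fs_out / rec$fs)
  t_in <- seq(0, n_in - 1) / rec$fs
  t_out <- seq(0, n_out - 1) / fs_out
  out <- apply(rec$samples, 2, function(col)
    stats::approx(t_in, col, xout = t_out, rule = 2)$y)
  dimnames(out) <- list(NULL, colnames(rec$samples))
  rec$samples <- out
  rec$fs <- fs_out
  rec
}

#' Run the full preprocessing chain on one trial
#'
#' rectify -> IEMG envelope -> unit normalization -> resample to the
#' angle rate.
#'
#' @param rec A raw `emg_recording`.
#' @param filter An [iemg_filter()].
#' @param stats Optional `norm_stats` (e.g. stored training-session
#'   statistics); `NULL` normalizes the trial by its own extrema.
#' @param fs_out Target rate in Hz.
#' @return An `envelope_signal` at `fs_out`.
#' @export
preprocess_trial <- function(rec, filter = iemg_filter(), stats = NULL,
                             fs_out = 120) {
  env <- envelope_filter(rectify(rec), filter)
  env <- normalize_unit(env, stats)
  resample_to_angle_rate(env, fs_out)
}

#' Preprocess every trial of a session with shared statistics
#'
#' Envelopes are computed per trial, the normalization extrema are pooled
#' over the whole session (unless `stats` supplies stored ones), and each
#' trial is then normalized and resampled.
#'
#' @param session An `emg_session`.
#' @param filter An [iemg_filter()].
#' @param stats Optional stored `norm_stats`.
#' @param fs_out Target rate in Hz.
#' @return List with `trials` (each a list of `env` envelope recording
#'   and `angles` recording) and the `stats` used.
#' @export
preprocess_session <- function(session, filter = iemg_filter(), stats = NULL,
                               fs_out = 120) {
  if (!inherits(session, "emg_session")) stop_data("session must be an emg_session")
  envs <- lapply(session$trials, function(tr)
    envelope_filter(rectify(tr$emg), filter))
  if (is.null(stats)) stats <- compute_norm_stats(envs)
  trials <- lapply(seq_along(envs), function(i) {
    env <- resample_to_angle_rate(normalize_unit(envs[[i]], stats), fs_out)
    list(env = env, angles = session$trials[[i]]$angles)
  })
  list(trials = trials, stats = stats)
}
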