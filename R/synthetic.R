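## Synthetic sEMG / kinematics generator.
##
## Real recordings pair 32-channel surface EMG at 500 Hz with three joint
## angles at 120 Hz while the subject cycles through a fixed motion
## sequence.  The generator reproduces that structure: smooth angle
## excursions following the trial paradigm, latent motion-primitive
## activations derived from the angles, and EMG synthesized per channel as
## band-limited carrier noise amplitude-modulated by a nonnegative spatial
## mixture of those activations.  A day-shift transform emulates the
## between-session changes (contact-impedance gain drift, sleeve rotation,
## noise-floor change) that motivate transfer-learning recalibration.

MOTIONS <- c("WF", "WE", "P", "S", "HG", "HO")
MOTION_JOINT <- c(WF = 1L, WE = 1L, P = 2L, S = 2L, HG = 3L, HO = 3L)
MOTION_SIGN <- c(WF = 1, WE = -1, P = 1, S = -1, HG = 1, HO = -1)
JOINT_NAMES <- c("WFWE", "PS", "HGHO")

#' Trial paradigm specification
#'
#' One trial starts at the central position (CP, all joints at 0 degrees)
#' and performs each motion in `motion_order` as a smooth excursion
#' CP -> peak -> CP, separated by rests at CP.  The default order performs
#' wrist flexion/extension twice, pronation/supination twice and hand
#' grip/open twice.  Flexion, pronation and grip are positive angles;
#' extension, supination and open are negative.
#'
#' @param motion_order Character vector of motion labels drawn from
#'   WF, WE, P, S, HG, HO.
#' @param hold_duration Seconds per excursion (CP to peak and back).
#' @param rest_duration Seconds of rest at CP before each motion and after
#'   the last one.
#' @param peak_angle Named numeric vector of peak angles in degrees for
#'   the six motions; signs must follow the convention above.
#' @param fs_angle Joint-angle sampling rate in Hz.
#' @param fs_emg EMG sampling rate in Hz.
#' @param angle_jitter_sd Standard deviation in degrees of additive
#'   measurement jitter on all three angle channels (0 = noiseless).
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(motion_order = c("WF", "WE", "WF", "WE",
                                           "P", "S", "P", "S",
                                           "HG", "HO", "HG", "HO"),
                          hold_duration = 2,
                          rest_duration = 1,
                          peak_angle = c(WF = 60, WE = -60, P = 70,
                                         S = -70, HG = 50, HO = -50),
                          fs_angle = 120,
                          fs_emg = 500,
                          angle_jitter_sd = 0) {
  if (!all(motion_order %in% MOTIONS))
    stop_config("unknown motion labels: ",
                paste(setdiff(motion_order, MOTIONS), collapse = ", "))
  if (hold_duration <= 0 || rest_duration <= 0)
    stop_config("hold_duration and rest_duration must be positive")
  if (fs_angle <= 0 || fs_emg <= 0)
    stop_config("sampling rates must be positive")
  if (!all(MOTIONS %in% names(peak_angle)))
    stop_config("peak_angle must name all six motions")
  peak_angle <- peak_angle[MOTIONS]
  bad <- sign(peak_angle) * MOTION_SIGN < 0
  if (any(bad))
    stop_config("peak_angle signs violate the convention (WF/P/HG >= 0, ",
                "WE/S/HO <= 0): ", paste(MOTIONS[bad], collapse = ", "))
  structure(list(motion_order = motion_order,
                 hold_duration = hold_duration,
                 rest_duration = rest_duration,
                 peak_angle = peak_angle,
                 fs_angle = fs_angle,
                 fs_emg = fs_emg,
                 angle_jitter_sd = angle_jitter_sd),
            class = "paradigm_spec")
}

#' Build the joint-angle trajectory for one trial
#'
#' Each motion in the paradigm becomes a raised-cosine pulse
#' `peak * (1 - cos(2*pi*t/T)) / 2` on its joint, so every excursion
#' leaves and returns to 0 degrees smoothly; the other two joints stay at
#' 0 (plus optional jitter).
#'
#' @param spec A [paradigm_spec()].
#' @param seed Optional integer seed for the jitter; `NULL` uses the
#'   current RNG stream.
#' @return An `angle_recording`: list with `angles` (time x 3 matrix in
#'   degrees, columns WFWE/PS/HGHO), `fs`, and `trial_id`.
#' @export
build_paradigm_angles <- function(spec, seed = NULL) {
  if (!inherits(spec, "paradigm_spec")) stop_config("spec must be a paradigm_spec")
  fs <- spec$fs_angle
  n_hold <- round(spec$hold_duration * fs)
  n_rest <- round(spec$rest_duration * fs)
  n_total <- n_rest + length(spec$motion_order) * (n_hold + n_rest)
  ang <- matrix(0, n_total, 3, dimnames = list(NULL, JOINT_NAMES))
  pulse <- 0.5 * (1 - cos(2 * pi * seq(0, n_hold - 1) / n_hold))
  pos <- n_rest
  for (m in spec$motion_order) {
    j <- MOTION_JOINT[[m]]
    ang[pos + seq_len(n_hold), j] <- spec$peak_angle[[m]] * pulse
    pos <- pos + n_hold + n_rest
  }
  if (spec$angle_jitter_sd > 0) {
    ang <- ang + with_seed(seed, matrix(stats::rnorm(length(ang),
                                                     sd = spec$angle_jitter_sd),
                                        nrow(ang), 3))
  }
  angle_recording(ang, fs = fs)
}

#' Construct an angle recording
#'
#' @param angles Time x 3 numeric matrix of joint angles in degrees.
#' @param fs Sampling rate in Hz.
#' @param trial_id Optional trial identifier.
#' @export
angle_recording <- function(angles, fs = 120, trial_id = NA) {
  check_matrix(angles, "angles", ncol = 3)
  colnames(angles) <- JOINT_NAMES
  structure(list(angles = angles, fs = fs, trial_id = trial_id),
            class = "angle_recording")
}

#' Construct an EMG recording
#'
#' @param samples Time x n_channels numeric matrix of EMG amplitudes.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Integer channel identifiers (default 1:ncol).
#' @param trial_id,session_id Optional identifiers.
#' @export
emg_recording <- function(samples, fs = 500, channel_ids = seq_len(ncol(samples)),
                          trial_id = NA, session_id = NA) {
  check_matrix(samples, "samples")
  if (fs <= 0) stop_config("fs must be positive")
  if (length(channel_ids) != ncol(samples))
    stop_config("channel_ids length must match column count")
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 trial_id = trial_id, session_id = session_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' @export
print.angle_recording <- function(x, ...) {
  cat(sprintf("<angle_recording> %d samples x 3 joints @ %g Hz (%.1f s)\n",
              nrow(x$angles), x$fs, nrow(x$angles) / x$fs))
  invisible(x)
}

#' Motion-primitive activations from joint angles
#'
#' Each of the six motion primitives (WF, WE, P, S, HG, HO) receives a
#' nonnegative activation equal to the excursion of its joint rectified in
#' its direction, scaled to peak 1.  Activations are exactly 0 at the
#' central position and peak together with the angle.
#'
#' @param angles An `angle_recording` or a time x 3 angle matrix (degrees).
#' @return Time x 6 nonnegative matrix, columns WF, WE, P, S, HG, HO.
#' @export
simulate_activations <- function(angles) {
  a <- if (inherits(angles, "angle_recording")) angles$angles else angles
  check_matrix(a, "angles", ncol = 3)
  act <- matrix(0, nrow(a), 6, dimnames = list(NULL, MOTIONS))
  for (m in MOTIONS) {
    exc <- MOTION_SIGN[[m]] * a[, MOTION_JOINT[[m]]]
    exc <- pmax(exc, 0)
    peak <- max(exc)
    act[, m] <- if (peak > 0) exc / peak else exc
  }
  act
}

#' Spatial mixing specification for EMG synthesis
#'
#' Defines how the six motion primitives project onto the 32 electrode
#' channels, plus the carrier-noise band and baseline noise floor.  The
#' default mixing matrix plants each primitive on a 2 x 2 block of one
#' face of the sleeve (positive-angle motions on the flexor face,
#' negative on the extensor face) and lets activity bleed onto
#' grid-neighbouring channels with gain `spatial_smoothness`.
#'
#' @param mixing_matrix Optional 32 x 6 nonnegative matrix (channels x
#'   primitives); `NULL` builds the default planted-block matrix.
#' @param spatial_smoothness Gain in \[0, 1) given to grid neighbours of
#'   planted channels in the default matrix.
#' @param carrier_band Length-2 Hz pair, pass band of the EMG-like
#'   carrier noise; must lie inside (0, fs_emg / 2).
#' @param noise_floor Baseline modulation amplitude common to all
#'   channels (arbitrary units).
#' @return An object of class `synergy_spec`.
#' @export
synergy_spec <- function(mixing_matrix = NULL, spatial_smoothness = 0.3,
                         carrier_band = c(20, 200), noise_floor = 0.02) {
  if (is.null(mixing_matrix))
    mixing_matrix <- default_mixing_matrix(spatial_smoothness)
  if (!is.matrix(mixing_matrix) || nrow(mixing_matrix) != 32 ||
      ncol(mixing_matrix) != 6)
    stop_config("mixing_matrix must be 32 x 6")
  if (any(mixing_matrix < 0)) stop_config("mixing_matrix must be nonnegative")
  if (any(colSums(mixing_matrix) <= 0))
    stop_config("every motion primitive must activate at least one channel")
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1])
    stop_config("carrier_band must be an increasing positive Hz pair")
  if (noise_floor < 0) stop_config("noise_floor must be nonnegative")
  colnames(mixing_matrix) <- MOTIONS
  structure(list(mixing_matrix = mixing_matrix,
                 spatial_smoothness = spatial_smoothness,
                 carrier_band = carrier_band,
                 noise_floor = noise_floor),
            class = "synergy_spec")
}

#' Default planted-block mixing matrix
#'
#' Channel sets driven by each primitive (gain 1), chosen as disjoint
#' 2 x 2 blocks so that weight-topography recovery can be validated
#' against known ground truth:
#' WF \{5, 6, 13, 14\}, P \{7, 8, 15, 16\}, HG \{21, 22, 29, 30\} on the
#' flexor face; WE \{1, 2, 9, 10\}, S \{3, 4, 11, 12\}, HO
#' \{17, 18, 25, 26\} on the extensor face.  Grid neighbours of planted
#' channels receive gain `smoothness`.
#'
#' @param smoothness Neighbour gain in \[0, 1).
#' @return 32 x 6 nonnegative matrix, columns WF, WE, P, S, HG, HO.
#' @export
default_mixing_matrix <- function(smoothness = 0.3) {
  planted <- list(WF = c(5, 6, 13, 14),  P = c(7, 8, 15, 16),
                  HG = c(21, 22, 29, 30), WE = c(1, 2, 9, 10),
                  S = c(3, 4, 11, 12),   HO = c(17, 18, 25, 26))
  lay <- channel_layout()
  m <- matrix(0, 32, 6, dimnames = list(NULL, MOTIONS))
  for (mo in MOTIONS) {
    chans <- planted[[mo]]
    m[chans, mo] <- 1
    for (ch in chans) {
      i <- which(lay$channel == ch)
      nb <- lay$channel[lay$side == lay$side[i] &
                          abs(lay$row - lay$row[i]) + abs(lay$col - lay$col[i]) == 1]
      idx <- setdiff(nb, chans)
      m[idx, mo] <- pmax(m[idx, mo], smoothness)
    }
  }
  m
}

#' Channels driven by each joint's motion primitives
#'
#' The ground-truth channel set per joint, read off the generative
#' mixing matrix: every channel with positive mixing gain for either of
#' the joint's two primitives (planted blocks plus their smoothness
#' bleed, which carries the same signal).  Used to validate
#' weight-topography recovery against known structure.
#'
#' @param synergy A [synergy_spec()]; defaults to the standard planted
#'   mixture.
#' @return List of three integer channel vectors named WFWE, PS, HGHO.
#' @export
planted_channels <- function(synergy = synergy_spec()) {
  mix <- synergy$mixing_matrix
  list(WFWE = which(mix[, "WF"] > 0 | mix[, "WE"] > 0),
       PS   = which(mix[, "P"] > 0 | mix[, "S"] > 0),
       HGHO = which(mix[, "HG"] > 0 | mix[, "HO"] > 0))
}

## Band-limited zero-mean unit-variance carrier noise, one column per channel.
make_carrier <- function(n, n_channels, band, fs) {
  if (band[2] >= fs / 2)
    stop_config("carrier_band upper edge ", band[2],
                " Hz is at or above Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  for (c in seq_len(n_channels)) {
    y <- signal::filter(bf, x[, c])
    s <- stats::sd(y)
    x[, c] <- if (s > 0) y / s else y
  }
  x
}

#' Synthesize raw-like multichannel EMG from primitive activations
#'
#' Per channel, zero-mean carrier noise band-limited to
#' `spec$carrier_band` is amplitude-modulated by
#' `mixing_matrix %*% activation + noise_floor`.  Activations sampled at
#' `fs_act` are linearly interpolated up to the EMG rate first.  The
#' rectified-and-lowpassed output therefore tracks the modulating signal,
#' which is what the preprocessing chain recovers.
#'
#' @param activations Time x 6 nonnegative matrix from
#'   [simulate_activations()].
#' @param spec A [synergy_spec()].
#' @param fs_emg Output sampling rate in Hz.
#' @param fs_act Sampling rate of `activations` in Hz.
#' @param seed Optional seed for the carrier noise.
#' @return An `emg_recording` at `fs_emg` with 32 channels.
#' @export
synthesize_emg <- function(activations, spec, fs_emg = 500, fs_act = 120,
                           seed = NULL) {
  if (!inherits(spec, "synergy_spec")) stop_config("spec must be a synergy_spec")
  check_matrix(activations, "activations", ncol = 6)
  if (any(activations < 0)) stop_config("activations must be nonnegative")
  n_in <- nrow(activations)
  n_out <- round(n_in * fs_emg / fs_act)
  t_in <- seq(0, n_in - 1) / fs_act
  t_out <- seq(0, n_out - 1) / fs_emg
  act_up <- apply(activations, 2, function(col)
    stats::approx(t_in, col, xout = t_out, rule = 2)$y)
  modulator <- act_up %*% t(spec$mixing_matrix) + spec$noise_floor
  carrier <- with_seed(seed,
                       make_carrier(n_out, 32, spec$carrier_band, fs_emg))
  emg_recording(carrier * modulator, fs = fs_emg)
}

#' Between-day distribution shift specification
#'
#' Models the changes typically seen when the sleeve is re-donned on a
#' later day: per-channel multiplicative gain change (contact impedance),
#' a rigid rotation of the sleeve by whole grid columns, and a change of
#' the baseline noise level.
#'
#' @param channel_gain Positive 32-vector of multiplicative gains.
#' @param layout_shift Integer column rotation, |shift| < 4.
#' @param noise_scale Factor >= 1 on the baseline noise floor (extra
#'   band-limited noise is injected to raise the floor; it cannot be
#'   removed once synthesized).
#' @param seed Integer seed for the injected noise.
#' @return An object of class `day_shift_spec`.
#' @export
day_shift_spec <- function(channel_gain = rep(1, 32), layout_shift = 0L,
                           noise_scale = 1, seed = 1L) {
  if (length(channel_gain) != 32 || any(channel_gain <= 0))
    stop_config("channel_gain must be 32 positive values")
  if (abs(layout_shift) >= 4) stop_config("|layout_shift| must be < 4")
  if (noise_scale < 1)
    stop_config("noise_scale must be >= 1 (noise can only be added)")
  structure(list(channel_gain = channel_gain,
                 layout_shift = as.integer(layout_shift),
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "day_shift_spec")
}

#' Random day-shift specification
#'
#' Convenience constructor drawing log-normal channel gains around 1.
#'
#' @param seed Integer seed.
#' @param gain_sdlog Standard deviation of log gains.
#' @param layout_shift Column rotation of the sleeve.
#' @param noise_scale Noise-floor factor (>= 1).
#' @export
random_day_shift <- function(seed = 1L, gain_sdlog = 0.4, layout_shift = 1L,
                             noise_scale = 2) {
  gains <- with_seed(seed, stats::rlnorm(32, meanlog = 0, sdlog = gain_sdlog))
  day_shift_spec(channel_gain = gains, layout_shift = layout_shift,
                 noise_scale = noise_scale, seed = seed)
}

#' Apply a between-day shift to a synthetic session
#'
#' EMG channels are remapped through the sleeve rotation, rescaled by the
#' per-channel gains, and (for `noise_scale > 1`) contaminated with extra
#' carrier noise of amplitude `noise_floor * (noise_scale - 1)`.  Angle
#' trajectories are untouched.  The identity specification is an exact
#' no-op.
#'
#' @param session An `emg_session` from [generate_session()].
#' @param shift A [day_shift_spec()].
#' @return A shifted `emg_session`.
#' @export
apply_day_shift <- function(session, shift) {
  if (!inherits(session, "emg_session")) stop_config("session must be an emg_session")
  if (!inherits(shift, "day_shift_spec")) stop_config("shift must be a day_shift_spec")
  src <- shift_permutation(shift$layout_shift)
  extra_amp <- session$synergy$noise_floor * (shift$noise_scale - 1)
  for (i in seq_along(session$trials)) {
    emg <- session$trials[[i]]$emg
    x <- emg$samples[, src, drop = FALSE]
    x <- sweep(x, 2, shift$channel_gain, `*`)
    if (extra_amp > 0) {
      extra <- with_seed(shift$seed + i,
                         make_carrier(nrow(x), 32, session$synergy$carrier_band,
                                      emg$fs)) * extra_amp
      x <- x + extra
    }
    colnames(x) <- colnames(emg$samples)
    session$trials[[i]]$emg$samples <- x
  }
  session$day_shift <- shift
  session
}

#' Generate a synthetic recording session
#'
#' Produces `n_trials` independent trials sharing one mixing matrix.
#' Trial i is generated under seed `seed + i`, so sessions are fully
#' reproducible while trials differ in their noise realizations.
#'
#' @param paradigm A [paradigm_spec()].
#' @param synergy A [synergy_spec()].
#' @param n_trials Number of trials (10 in the initial-experiment design,
#'   5 in the reduced second-day design).
#' @param seed Integer base seed.
#' @return An object of class `emg_session`: list with `trials` (each a
#'   list of `emg`, `angles`, `activations`), `paradigm`, `synergy`,
#'   `seed`, and `day_shift` (NULL until [apply_day_shift()]).
#' @export
generate_session <- function(paradigm = paradigm_spec(),
                             synergy = synergy_spec(),
                             n_trials = 10, seed = 1L) {
  if (n_trials < 1) stop_config("n_trials must be >= 1")
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trials[[i]] <- with_seed(seed + i, {
      ang <- build_paradigm_angles(paradigm, seed = NULL)
      ang$trial_id <- i
      act <- simulate_activations(ang)
      emg <- synthesize_emg(act, synergy, fs_emg = paradigm$fs_emg,
                            fs_act = paradigm$fs_angle, seed = NULL)
      emg$trial_id <- i
      list(emg = emg, angles = ang, activations = act)
    })
  }
  structure(list(trials = trials, paradigm = paradigm, synergy = synergy,
                 seed = seed, day_shift = NULL),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("<emg_session> %d trials, %d channels @ %g Hz, angles @ %g Hz%s\n",
              length(x$trials), ncol(x$trials[[1]]$emg$samples),
              x$paradigm$fs_emg, x$paradigm$fs_angle,
              if (!is.null(x$day_shift)) " [day-shifted]" else ""))
  invisible(x)
}
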