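# Synthetic multi-subject, multi-session sEMG generator.
#
# The surface EMG carrier is amplitude-modulated band-limited Gaussian noise
# (20-450 Hz): each gesture drives a spatial activation pattern over a ring of
# electrodes, modulated by a trapezoidal onset/offset envelope, on top of a
# broadband noise floor and 50 Hz power-line interference.  Domain shift has
# two dials: subject-level pattern divergence (circular pattern offset plus
# multiplicative jitter) and session-level electrode displacement (continuous
# circular shift of the ring, in channel units).

#' Configuration for the synthetic sEMG generator
#'
#' Defines the structure (subjects, sessions, gestures, repetitions, channels,
#' timing) and the domain-shift dials of a synthetic recording campaign.  The
#' defaults emulate a two-session acquisition of seven grasps with eight
#' electrodes equally spaced around the forearm: each movement repetition
#' lasts 5 s and is followed by 3 s of rest, sampled at 2 kHz.
#'
#' @param n_subjects Number of subjects.
#' @param n_sessions Number of acquisition sessions per subject.
#' @param n_gestures Number of movement classes `G` (rest excluded; rest is
#'   always label 0).
#' @param n_repetitions Repetitions of each gesture per session.
#' @param n_channels Number of ring-mounted electrodes `C`.
#' @param fs Sampling rate in Hz; must exceed 900 so the 20-450 Hz carrier
#'   band is representable.
#' @param movement_s,rest_s Movement and rest durations in seconds.
#' @param ramp_s Envelope ramp duration in seconds; `2 * ramp_s` must be less
#'   than `movement_s`.
#' @param subject_sigma Log-scale spread of the per-entry multiplicative
#'   jitter of a subject's activation pattern (how far individual muscle
#'   recruitment departs from the gesture prototypes).
#' @param subject_rot Spread, in channels, of the subject-level circular
#'   offset of the whole pattern around the ring (anatomical placement
#'   variation between subjects).
#' @param session_shift_sigma Spread of the per-session electrode displacement
#'   in continuous channel units; session 1 is every subject's reference
#'   placement (offset 0).
#' @param gain_sigma Log-scale spread of per-channel gains.
#' @param rep_sigma Log-scale spread of the per-repetition amplitude jitter
#'   (contraction-strength variability between repetitions; this is what
#'   makes additional training repetitions informative).
#' @param noise_floor Baseline broadband noise amplitude.
#' @param noise_sigma Log-scale spread of the per-subject, per-channel noise
#'   floor (electrode-contact quality differences between subjects).
#' @param gamma_sigma Log-scale spread of the per-subject, per-channel
#'   amplitude-compression exponent (electrode-tissue nonlinearity: channel
#'   `c` of a subject records `sign(x) |x|^gamma_c`).  This shift is monotone
#'   per channel, so it warps every windowed feature monotonically -- the
#'   domain-shift component that threshold re-selection can recover.
#' @param interference_amp Amplitude of the 50 Hz power-line component.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   recordings.
#' @return An object of class `emg_generator_config`.
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_gestures = 3, seed = 7)
#' cfg$n_channels
#' @export
generator_config <- function(n_subjects = 10, n_sessions = 2, n_gestures = 7,
                             n_repetitions = 6, n_channels = 8, fs = 2000,
                             movement_s = 5, rest_s = 3, ramp_s = 0.5,
                             subject_sigma = 0.8, subject_rot = 0.6,
                             session_shift_sigma = 0.5,
                             gain_sigma = 0.4, rep_sigma = 0.4,
                             noise_floor = 1.5, noise_sigma = 0.6,
                             gamma_sigma = 0, interference_amp = 0.1,
                             seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
    n_gestures = as.integer(n_gestures),
    n_repetitions = as.integer(n_repetitions),
    n_channels = as.integer(n_channels), fs = fs,
    movement_s = movement_s, rest_s = rest_s, ramp_s = ramp_s,
    subject_sigma = subject_sigma, subject_rot = subject_rot,
    session_shift_sigma = session_shift_sigma,
    gain_sigma = gain_sigma, rep_sigma = rep_sigma, noise_floor = noise_floor,
    noise_sigma = noise_sigma, gamma_sigma = gamma_sigma,
    interference_amp = interference_amp, seed = as.integer(seed)
  )
  counts <- c("n_subjects", "n_sessions", "n_gestures", "n_repetitions",
              "n_channels")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) stop(nm, " must be >= 1")
  }
  if (cfg$fs <= 900) {
    stop("fs must exceed 900 Hz so the 20-450 Hz carrier band is representable")
  }
  if (cfg$movement_s <= 0 || cfg$rest_s <= 0 || cfg$ramp_s <= 0) {
    stop("movement_s, rest_s and ramp_s must be positive")
  }
  if (2 * cfg$ramp_s >= cfg$movement_s) {
    stop("2 * ramp_s must be smaller than movement_s")
  }
  for (nm in c("subject_sigma", "subject_rot", "session_shift_sigma",
               "gain_sigma",
               "rep_sigma", "noise_floor", "noise_sigma", "gamma_sigma",
               "interference_amp")) {
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  }
  structure(cfg, class = "emg_generator_config")
}

#' @export
print.emg_generator_config <- function(x, ...) {
  cat("sEMG generator config:", x$n_subjects, "subjects x", x$n_sessions,
      "sessions,", x$n_gestures, "gestures x", x$n_repetitions,
      "repetitions,", x$n_channels, "channels @", x$fs, "Hz\n")
  cat(sprintf("  movement %g s + rest %g s (ramp %g s)\n",
              x$movement_s, x$rest_s, x$ramp_s))
  cat(sprintf(
    "  dials: jitter %g, rot %g ch, session %g ch, gain %g, rep %g, floor %g, 50 Hz %g\n",
    x$subject_sigma, x$subject_rot, x$session_shift_sigma, x$gain_sigma,
    x$rep_sigma, x$noise_floor, x$interference_amp))
  invisible(x)
}

#' Gesture prototype activation patterns over the electrode ring
#'
#' Each gesture's prototype is a circular Gaussian bump over the `C`-channel
#' ring (bump centres spaced evenly over the ring, widths drawn per gesture)
#' plus a uniform floor, with each row normalized to maximum 1.  Deterministic
#' in `config$seed`.
#'
#' @param config An [generator_config()] object.
#' @param floor Uniform activation floor added before normalization.
#' @param centers,widths Optional explicit bump centres (ring coordinates in
#'   `[0, C)`) and widths (channels), one per gesture; by default centres are
#'   evenly spaced and widths are drawn uniformly in `[0.8, 1.6]`.
#' @return A `G x C` matrix of non-negative activations, row maxima 1.
#' @export
make_prototypes <- function(config, floor = 0.1, centers = NULL,
                            widths = NULL) {
  stopifnot(inherits(config, "emg_generator_config"))
  G <- config$n_gestures
  C <- config$n_channels
  if (is.null(centers)) centers <- (seq_len(G) - 1) * C / G
  if (is.null(widths)) {
    widths <- with_local_seed(mix_seed(config$seed, 101),
                              runif(G, 1.2, 2.4))
  }
  stopifnot(length(centers) == G, length(widths) == G, all(widths > 0))
  A <- matrix(0, G, C)
  ch <- seq_len(C) - 1
  for (g in seq_len(G)) {
    d <- abs(((ch - centers[g] + C / 2) %% C) - C / 2)  # ring distance
    A[g, ] <- exp(-d^2 / (2 * widths[g]^2)) + floor
  }
  A / apply(A, 1, max)
}

#' Circularly shift an activation pattern along the electrode ring
#'
#' Resamples the columns of an activation matrix at a continuous circular
#' offset by linear interpolation between adjacent ring channels.  An integer
#' offset is an exact circular permutation of the columns.  This is the
#' electrode-displacement model: channel `c` of the shifted pattern reads the
#' field at ring coordinate `c + offset`.
#'
#' @param activation A `G x C` matrix.
#' @param offset Displacement in continuous channel units (any real number).
#' @return The shifted `G x C` matrix.
#' @export
shift_activation <- function(activation, offset) {
  C <- ncol(activation)
  i0 <- base::floor(offset)
  frac <- offset - i0
  idx1 <- ((seq_len(C) - 1 + i0) %% C) + 1
  idx2 <- ((seq_len(C) + i0) %% C) + 1
  (1 - frac) * activation[, idx1, drop = FALSE] +
    frac * activation[, idx2, drop = FALSE]
}

#' Derive a subject-specific activation model
#'
#' A subject's activation matrix is the gesture prototype set resampled at a
#' subject-specific circular offset (linear interpolation over the ring) with
#' multiplicative log-normal jitter of spread `subject_sigma` applied per
#' entry, then re-normalized to row maxima 1.  Channel gains are log-normal
#' with spread `gain_sigma`.  Per-session electrode displacements are normal
#' with spread `session_shift_sigma`; session 1 is the reference placement
#' (offset exactly 0).
#'
#' @param prototypes Matrix from [make_prototypes()].
#' @param subject_index Subject number (1-based).
#' @param config An [generator_config()] object.
#' @return An object of class `emg_subject_model` with fields `activation`
#'   (`G x C`), `channel_gain` (length `C`) and `electrode_offset`
#'   (length `n_sessions`).
#' @export
derive_subject <- function(prototypes, subject_index, config) {
  stopifnot(inherits(config, "emg_generator_config"))
  G <- nrow(prototypes)
  C <- ncol(prototypes)
  with_local_seed(mix_seed(config$seed, 202, subject_index), {
    off <- rnorm(1, 0, config$subject_rot %||% config$subject_sigma)
    act <- shift_activation(prototypes, off)
    jit <- matrix(exp(rnorm(G * C, 0, config$subject_sigma)), G, C)
    act <- act * jit
    act <- act / apply(act, 1, max)
    gain <- exp(rnorm(C, 0, config$gain_sigma))
    chan_noise <- exp(rnorm(C, 0, config$noise_sigma))
    chan_gamma <- exp(rnorm(C, 0, config$gamma_sigma %||% 0))
    sess_off <- rnorm(config$n_sessions, 0, config$session_shift_sigma)
    sess_off[1] <- 0
    structure(list(activation = act, channel_gain = gain,
                   channel_noise = chan_noise, channel_gamma = chan_gamma,
                   electrode_offset = sess_off,
                   subject_index = as.integer(subject_index)),
              class = "emg_subject_model")
  })
}

new_recording <- function(emg, label, repetition, subject_id, session_id, fs) {
  stopifnot(nrow(emg) == length(label), length(label) == length(repetition))
  structure(list(emg = emg, label = as.integer(label),
                 repetition = as.integer(repetition),
                 subject_id = subject_id, session_id = session_id, fs = fs),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "sEMG recording: subject %s session %s, %d samples x %d channels @ %g Hz\n",
    x$subject_id, x$session_id, nrow(x$emg), ncol(x$emg), x$fs))
  g <- sort(unique(x$label[x$label > 0]))
  cat("  gestures:", paste(g, collapse = ", "),
      "| repetitions:", max(x$repetition), "\n")
  invisible(x)
}

#' Synthesize one labeled recording session
#'
#' Emits, for each gesture and repetition, a movement block of `movement_s`
#' seconds followed by `rest_s` seconds of rest (blocks ordered by gesture,
#' then repetition).  During movement, channel `c` carries
#' `channel_gain[c] * A[g, c] * e(t) * w_c(t)` where `A` is the subject
#' activation shifted by the session's electrode offset, `e(t)` a trapezoidal
#' envelope with `ramp_s` ramps, and `w_c(t)` unit-variance Gaussian noise
#' band-pass filtered to 20-450 Hz (4th-order Butterworth, forward-backward).
#' A broadband noise floor and a 50 Hz sinusoid (shared amplitude, per-channel
#' phase) are added everywhere.  Movement samples, including the ramps, carry
#' the gesture label; rest samples have label and repetition 0.
#'
#' @param subject An `emg_subject_model` from [derive_subject()].
#' @param session_id Session number (1-based).
#' @param config An [generator_config()] object.
#' @return An object of class `emg_recording` with fields `emg`
#'   (`n_samples x C`), `label`, `repetition`, `subject_id`, `session_id`,
#'   `fs`.
#' @export
synthesize_session <- function(subject, session_id, config) {
  stopifnot(inherits(subject, "emg_subject_model"),
            inherits(config, "emg_generator_config"))
  if (config$fs <= 900) {
    stop("fs too low for the 450 Hz carrier band edge")
  }
  fs <- config$fs
  G <- config$n_gestures
  R <- config$n_repetitions
  C <- config$n_channels
  n_mov <- round(config$movement_s * fs)
  n_rest <- round(config$rest_s * fs)
  block <- n_mov + n_rest
  n <- G * R * block

  A <- shift_activation(subject$activation,
                        subject$electrode_offset[session_id])

  # trapezoidal envelope over the movement part of a block
  t_mov <- (seq_len(n_mov) - 1) / fs
  env <- pmin(1, t_mov / config$ramp_s,
              (config$movement_s - t_mov) / config$ramp_s)
  env <- pmax(env, 0)
  env_block <- c(env, numeric(n_rest))

  gest_of_block <- rep(seq_len(G), each = R)             # block order: g, then r
  rep_of_block <- rep(seq_len(R), times = G)
  label <- rep(gest_of_block, each = block) *
    rep(c(rep(1L, n_mov), rep(0L, n_rest)), G * R)
  repetition <- rep(rep_of_block, each = block) *
    rep(c(rep(1L, n_mov), rep(0L, n_rest)), G * R)

  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  tt <- (seq_len(n) - 1) / fs
  blk_idx <- rep(seq_len(G * R), each = block)
  env_full <- rep(env_block, G * R)

  emg <- with_local_seed(
    mix_seed(config$seed, 303, subject$subject_index, session_id), {
      phi <- runif(C, 0, 2 * pi)
      # contraction-strength variability between repetitions (shared across
      # channels within a block)
      rep_amp <- exp(rnorm(G * R, 0, config$rep_sigma))
      out <- matrix(0, n, C)
      period <- fs / 50  # 50 Hz cycle length in samples
      for (c in seq_len(C)) {
        carrier <- cpp_filtfilt(bf$b, bf$a, rnorm(n))
        amp <- subject$channel_gain[c] *
          (rep_amp * A[gest_of_block, c])[blk_idx] * env_full
        hum <- if (period == round(period)) {
          rep_len(sin(2 * pi * 50 * tt[seq_len(period)] + phi[c]), n)
        } else {
          sin(2 * pi * 50 * tt + phi[c])
        }
        floor_c <- config$noise_floor *
          (subject$channel_noise[c] %||% 1)
        sig <- amp * carrier + floor_c * rnorm(n)
        g <- (subject$channel_gamma %||% rep(1, C))[c]
        if (g != 1) sig <- sign(sig) * abs(sig)^g
        out[, c] <- sig + config$interference_amp * hum
      }
      out
    })

  new_recording(emg, label, repetition, subject$subject_index, session_id, fs)
}

#' Synthesize a full multi-subject, multi-session dataset
#'
#' @param config An [generator_config()] object.
#' @param floor Activation floor passed to [make_prototypes()].
#' @return A list of `emg_recording` objects (class `emg_dataset`), ordered by
#'   subject then session, with the generating config attached as an
#'   attribute.
#' @export
synthesize_dataset <- function(config, floor = 0.1) {
  protos <- make_prototypes(config, floor = floor)
  out <- list()
  for (s in seq_len(config$n_subjects)) {
    subj <- derive_subject(protos, s, config)
    for (k in seq_len(config$n_sessions)) {
      out[[sprintf("s%d_sess%d", s, k)]] <-
        synthesize_session(subj, k, config)
    }
  }
  structure(out, class = "emg_dataset", config = config)
}

#' @export
print.emg_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("sEMG dataset:", length(x), "recordings\n")
  if (!is.null(cfg)) print(cfg)
  invisible(x)
}
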