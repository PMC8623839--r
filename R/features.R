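# Signal conditioning and windowed feature extraction: spectral Hampel
# power-line removal, train-statistics standardization, 200 ms / 10 ms sliding
# windows, and the per-window MAV / VAR / mDWT feature set.

#' Remove power-line interference with a spectral Hampel filter
#'
#' Per channel, the discrete Fourier transform is computed and, within a
#' `band_hz` band around each harmonic of `base_hz`, magnitude bins deviating
#' from the local median (11-bin neighborhood) by more than 3 median absolute
#' deviations are replaced by that median, preserving phase.  The conjugate
#' symmetry of the spectrum is maintained, so the output is real and of the
#' same length.
#'
#' @param emg Numeric matrix (`samples x channels`) or vector.
#' @param fs Sampling rate in Hz.
#' @param base_hz Power-line fundamental (default 50 Hz).
#' @param n_harmonics Number of harmonics to clean; the highest band must lie
#'   below Nyquist.
#' @param band_hz Half-width of the cleaned band around each harmonic.
#' @param k Neighborhood size for the running median (odd).
#' @param t0 Outlier threshold in scaled median absolute deviations.
#' @return Filtered matrix of the same dimensions.
#' @export
hampel_powerline <- function(emg, fs, base_hz = 50, n_harmonics = 3,
                             band_hz = 2, k = 11, t0 = 3) {
  if (is.vector(emg)) emg <- matrix(emg, ncol = 1)
  stopifnot(k %% 2 == 1)
  if (base_hz * n_harmonics + band_hz >= fs / 2) {
    stop("harmonic band extends beyond Nyquist: reduce n_harmonics")
  }
  n <- nrow(emg)
  if (n == 0) return(emg)
  half <- k %/% 2
  FT <- mvfft(emg)
  pos_max <- base::floor(n / 2) + 1  # last non-redundant bin
  # harmonic bands on the positive-frequency side
  band_list <- lapply(base_hz * seq_len(n_harmonics), function(h) {
    lo <- max(2L, base::ceiling((h - band_hz) * n / fs) + 1L)
    hi <- min(pos_max, base::floor((h + band_hz) * n / fs) + 1L)
    if (lo > hi) NULL else lo:hi
  })
  for (ch in seq_len(ncol(emg))) {
    for (b in band_list) {
      if (is.null(b)) next
      nb <- outer(b, -half:half, "+")
      nb[nb < 2] <- 2L
      nb[nb > pos_max] <- pos_max
      rng <- min(nb):max(nb)
      magslice <- Mod(FT[rng, ch])
      M <- matrix(magslice[nb - rng[1] + 1L], nrow = length(b))
      Msort <- matrix(M[order(row(M), M)], nrow = length(b), byrow = TRUE)
      med <- Msort[, half + 1]
      A <- abs(M - med)
      Asort <- matrix(A[order(row(A), A)], nrow = length(b), byrow = TRUE)
      madv <- 1.4826 * Asort[, half + 1]
      magb <- magslice[b - rng[1] + 1L]
      bad <- abs(magb - med) > t0 * madv
      if (any(bad)) {
        i <- b[bad]
        FT[i, ch] <- med[bad] * exp(1i * Arg(FT[i, ch]))
        mirror <- n + 2L - i
        keep <- mirror != i & mirror <= n
        FT[mirror[keep], ch] <- Conj(FT[i[keep], ch])
      }
    }
  }
  out <- Re(mvfft(FT, inverse = TRUE)) / n
  dimnames(out) <- dimnames(emg)
  out
}

#' Fit per-channel standardization statistics
#'
#' @param train_emg Numeric matrix whose rows are the training samples.
#' @return List with `mean` and `sd` (unbiased) per channel.
#' @export
standardizer_fit <- function(train_emg) {
  if (is.vector(train_emg)) train_emg <- matrix(train_emg, ncol = 1)
  if (nrow(train_emg) == 0) stop("empty training data for standardization")
  mu <- colMeans(train_emg)
  n <- nrow(train_emg)
  ss <- colSums(train_emg^2) - n * mu^2
  sdv <- sqrt(pmax(ss, 0) / max(n - 1, 1))
  list(mean = mu, sd = sdv)
}

#' Apply standardization statistics to a signal
#'
#' Channels with zero (or undefined) training standard deviation map to 0.
#'
#' @param stats List from [standardizer_fit()].
#' @param emg Matrix with the same channel count.
#' @return Standardized matrix.
#' @export
standardizer_apply <- function(stats, emg) {
  if (is.vector(emg)) emg <- matrix(emg, ncol = 1)
  stopifnot(ncol(emg) == length(stats$mean))
  out <- cpp_standardize(emg, stats$mean, stats$sd)
  dimnames(out) <- dimnames(emg)
  out
}

#' Standardize a signal using statistics estimated on training data only
#'
#' @param train_emg Matrix the statistics are estimated on.
#' @param apply_emg Matrix the statistics are applied to (same channel count).
#' @return Standardized `apply_emg`.
#' @export
standardize <- function(train_emg, apply_emg) {
  standardizer_apply(standardizer_fit(train_emg), apply_emg)
}

#' Sliding windows over a recording
#'
#' Windows of `window_ms` with increment `step_ms`, starting at multiples of
#' the step from sample 1.  The window label is the majority vote of the
#' sample labels in the window, with ties resolved to rest (0); the window
#' repetition is assigned analogously.
#'
#' @param recording An `emg_recording`.
#' @param window_ms,step_ms Window length and increment in milliseconds.
#' @param repetition Optional per-sample repetition stream overriding the
#'   recording's (used by the experiment protocols to attach rest periods to
#'   the preceding movement repetition).
#' @return A list of class `emg_windows` with `starts` (1-based sample
#'   starts), `W`, `S`, per-window `label` and `repetition`, and `n_windows`.
#'   A recording shorter than one window yields zero windows.
#' @export
sliding_windows <- function(recording, window_ms = 200, step_ms = 10,
                            repetition = NULL) {
  fs <- recording$fs
  W <- round(window_ms * fs / 1000)
  S <- round(step_ms * fs / 1000)
  stopifnot(W >= 1, S >= 1)
  n <- nrow(recording$emg)
  if (n < W) {
    starts0 <- integer(0)
  } else {
    starts0 <- seq.int(0L, n - W, by = S)
  }
  rep_stream <- as.integer(repetition %||% recording$repetition)
  lab <- recording$label
  wl <- if (length(starts0)) {
    cpp_window_majority(lab, starts0, W, max(lab, 0L))
  } else integer(0)
  wr <- if (length(starts0)) {
    cpp_window_majority(rep_stream, starts0, W, max(rep_stream, 0L))
  } else integer(0)
  structure(list(starts = starts0 + 1L, W = W, S = S, label = wl,
                 repetition = wr, n_windows = length(starts0)),
            class = "emg_windows")
}

#' Extract one window from a recording
#'
#' @param recording An `emg_recording`.
#' @param windows An `emg_windows` index from [sliding_windows()].
#' @param i Window number.
#' @return A `W x C` matrix of samples.
#' @export
get_window <- function(recording, windows, i) {
  s <- windows$starts[i]
  recording$emg[s:(s + windows$W - 1), , drop = FALSE]
}

#' Mean absolute value per channel
#' @param window A `W x C` matrix (or vector for one channel).
#' @return Numeric vector of length `C`.
#' @export
mav <- function(window) {
  if (is.vector(window)) window <- matrix(window, ncol = 1)
  if (nrow(window) == 0) stop("empty window")
  colMeans(abs(window))
}

#' Unbiased sample variance per channel
#'
#' Variance about the window mean with divisor `W - 1`.
#'
#' @param window A `W x C` matrix (or vector for one channel).
#' @return Numeric vector of length `C`.
#' @export
win_var <- function(window) {
  if (is.vector(window)) window <- matrix(window, ncol = 1)
  if (nrow(window) < 2) stop("variance needs at least 2 samples per window")
  apply(window, 2, stats::var)
}

#' Marginal discrete wavelet transform per channel
#'
#' Multi-level periodized discrete wavelet decomposition; the marginal of each
#' detail level (shallow to deep) and of the final approximation is the sum of
#' the absolute coefficients at that level.  Marginals are concatenated per
#' channel: `d1, ..., dL, approximation` for channel 1, then channel 2, etc.
#'
#' @param window A `W x C` matrix (or vector for one channel).
#' @param wavelet Daubechies wavelet name (`"db1"`, `"db2"`, `"db4"`,
#'   `"db7"`).
#' @param levels Decomposition depth.
#' @return Numeric vector of length `C * (levels + 1)`.
#' @export
mdwt <- function(window, wavelet = "db7", levels = 3) {
  if (is.vector(window)) window <- matrix(window, ncol = 1)
  W <- nrow(window)
  filt <- db_filters(wavelet)
  if (W < length(filt$lo)) {
    stop("window shorter than the wavelet support (", length(filt$lo),
         " samples)")
  }
  if (W < 2^levels) stop("levels too deep for a window of ", W, " samples")
  X <- cpp_window_features(window, 0L, W, filt$lo, filt$hi, as.integer(levels))
  C <- ncol(window)
  as.numeric(X[1, (2 * C + 1):(C * (2 + levels + 1))])
}

#' Windowed feature extraction for a recording
#'
#' Pipeline: optional spectral Hampel power-line removal, standardization with
#' caller-supplied statistics, sliding windows, then per-window concatenation
#' of MAV, VAR and mDWT marginals.  Column layout (fixed):
#' `mav` for channels `1..C`, then `var` for channels `1..C`, then per channel
#' the mDWT marginals (`L` detail levels shallow to deep, then the
#' approximation), giving `d = C * (2 + levels + 1)` features.
#'
#' @param recording An `emg_recording`.
#' @param window_ms,step_ms Window length and increment in milliseconds.
#' @param hampel Apply [hampel_powerline()] before windowing.
#' @param standardizer Optional statistics from [standardizer_fit()]; supplied
#'   by the caller so they always come from training data only.
#' @param wavelet,levels mDWT configuration.
#' @param repetition Optional per-sample repetition stream override (see
#'   [sliding_windows()]).
#' @return An object of class `emg_features` with fields `X` (`N x d`), `y`,
#'   `repetition`, `subject_id`, `session_id`, `fs`, `window_ms`, `step_ms`
#'   and `feature_names`.
#' @export
extract_features <- function(recording, window_ms = 200, step_ms = 10,
                             hampel = FALSE, standardizer = NULL,
                             wavelet = "db7", levels = 3, repetition = NULL) {
  emg <- recording$emg
  if (hampel) emg <- hampel_powerline(emg, recording$fs)
  if (!is.null(standardizer)) emg <- standardizer_apply(standardizer, emg)
  rec <- recording
  rec$emg <- emg
  win <- sliding_windows(rec, window_ms, step_ms, repetition = repetition)
  C <- ncol(emg)
  filt <- db_filters(wavelet)
  if (win$W < length(filt$lo) || win$W < 2^levels) {
    stop("window too short for the requested wavelet decomposition")
  }
  X <- if (win$n_windows > 0) {
    cpp_window_features(emg, win$starts - 1L, win$W, filt$lo, filt$hi,
                        as.integer(levels))
  } else {
    matrix(numeric(0), 0, C * (2 + levels + 1))
  }
  fn <- c(paste0("mav_ch", seq_len(C)), paste0("var_ch", seq_len(C)),
          as.vector(vapply(seq_len(C), function(ch) {
            c(paste0("mdwt_ch", ch, "_d", seq_len(levels)),
              paste0("mdwt_ch", ch, "_a"))
          }, character(levels + 1))))
  colnames(X) <- fn
  structure(list(X = X, y = win$label, repetition = win$repetition,
                 subject_id = recording$subject_id,
                 session_id = recording$session_id, fs = recording$fs,
                 window_ms = window_ms, step_ms = step_ms,
                 feature_names = fn),
            class = "emg_features")
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("windowed sEMG features: %d windows x %d features (%g/%g ms)\n",
              nrow(x$X), ncol(x$X), x$window_ms, x$step_ms))
  invisible(x)
}

#' Subsample a training feature set at regular intervals
#'
#' Keeps rows 1, 1 + factor, 1 + 2 factor, ... (row order preserved); used to
#' thin training windows by a factor of 10 while test windows stay at the full
#' window rate.
#'
#' @param features An `emg_features` object.
#' @param factor Subsampling stride (>= 1).
#' @return The thinned `emg_features`.
#' @export
subsample_train <- function(features, factor = 10) {
  stopifnot(factor >= 1)
  n <- nrow(features$X)
  keep <- if (n == 0) integer(0) else seq.int(1L, n, by = as.integer(factor))
  features_subset(features, keep)
}

# Row subset of an emg_features object (keeps per-row metadata in step).
features_subset <- function(features, idx) {
  features$X <- features$X[idx, , drop = FALSE]
  features$y <- features$y[idx]
  features$repetition <- features$repetition[idx]
  for (nm in c("subject", "session")) {
    if (!is.null(features[[nm]]) && length(features[[nm]]) > 0) {
      features[[nm]] <- features[[nm]][idx]
    }
  }
  features
}
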