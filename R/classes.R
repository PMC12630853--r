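# S3 containers shared by all modules. These are deliberately light-weight
# lists with validation at construction, in the style of base-R analysis
# packages: a `power_spectrum` is the unit of model fitting, an `eeg_signal`
# wraps a channels-by-time matrix, and a `hypnogram` holds 30-s stage labels.

#' Construct a power spectrum
#'
#' @param freqs Strictly increasing frequency grid in Hz.
#' @param powers Linear power values (e.g. uV^2/Hz), non-negative, either a
#'   vector matching `freqs` or a matrix with `length(freqs)` rows (one
#'   column per channel).
#' @param settings Optional list recording estimation provenance.
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, powers, settings = list()) {
  freqs <- as.numeric(freqs)
  if (any(!is.finite(freqs)) || any(diff(freqs) <= 0)) {
    stopf("`freqs` must be finite and strictly increasing")
  }
  if (is.matrix(powers)) {
    if (nrow(powers) != length(freqs)) {
      stopf("`powers` matrix must have length(freqs) rows")
    }
  } else {
    powers <- as.numeric(powers)
    if (length(powers) != length(freqs)) {
      stopf("`freqs` and `powers` must have equal length")
    }
  }
  if (any(powers < 0, na.rm = TRUE)) {
    stopf("`powers` must be non-negative")
  }
  structure(list(freqs = freqs, powers = powers, settings = settings),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  nch <- if (is.matrix(x$powers)) ncol(x$powers) else 1L
  cat(sprintf("<power_spectrum> %d frequencies (%.3g-%.3g Hz), %d channel(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), nch))
  invisible(x)
}

#' Construct a continuous signal
#'
#' @param samples Numeric vector (one channel) or channels-by-time matrix,
#'   in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional channel names.
#' @param start_time_s Recording start time in seconds (default 0).
#' @return An object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, channel_labels = NULL, start_time_s = 0) {
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (any(!is.finite(samples))) stopf("`samples` must be finite")
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stopf("`channel_labels` must match the number of channels")
  }
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 start_time_s = start_time_s),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

# Duration in seconds.
signal_duration <- function(signal) ncol(signal$samples) / signal$fs

# Extract one channel as a numeric vector; accepts index or label.
signal_channel <- function(signal, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, signal$channel_labels)
    if (is.na(channel)) stopf("unknown channel label")
  }
  signal$samples[channel, ]
}

#' Construct a hypnogram
#'
#' An ordered sequence of 30-s sleep stage labels with an epoch-to-time
#' mapping. Labels are normalized to Wake/N1/N2/N3/REM.
#'
#' @param stages Character vector of stage labels, one per epoch.
#' @param epoch_s Epoch length in seconds (default 30).
#' @param start_time_s Time of the first epoch onset (default 0).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30, start_time_s = 0) {
  stages <- canonical_stage(stages)
  check_number(epoch_s, "epoch_s", lower = .Machine$double.eps)
  structure(list(stages = stages, epoch_s = epoch_s,
                 start_time_s = start_time_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = sleep_stages()))
  cat(sprintf("<hypnogram> %d epochs x %g s (%s)\n", length(x$stages),
              x$epoch_s,
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

# Onset time (s) of epoch i (1-based).
epoch_onset <- function(hyp, i) hyp$start_time_s + (i - 1) * hyp$epoch_s

#' Construct an event table
#'
#' @param onset_s Event onsets in seconds from recording start.
#' @param category Character labels (e.g. stimulus categories).
#' @return A [tibble::tibble] with class `event_table` prepended.
#' @export
event_table <- function(onset_s, category = rep("stim", length(onset_s))) {
  if (length(onset_s) && any(!is.finite(onset_s))) {
    stopf("event onsets must be finite")
  }
  out <- tibble::tibble(onset_s = as.numeric(onset_s),
                        category = as.character(category))
  class(out) <- c("event_table", class(out))
  out
}

#' Construct a spectrogram
#'
#' @param times Window time stamps in seconds (window centers).
#' @param freqs Frequency grid in Hz.
#' @param power Frequencies-by-times matrix of linear power.
#' @param settings Provenance list.
#' @return An object of class `spectrogram`.
#' @export
spectrogram <- function(times, freqs, power, settings = list()) {
  if (!is.matrix(power) || nrow(power) != length(freqs) ||
      ncol(power) != length(times)) {
    stopf("`power` must be a length(freqs) x length(times) matrix")
  }
  if (any(diff(times) <= 0) || any(diff(freqs) <= 0)) {
    stopf("`times` and `freqs` must be strictly increasing")
  }
  structure(list(times = as.numeric(times), freqs = as.numeric(freqs),
                 power = power, settings = settings),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs (%.3g-%.3g Hz) x %d windows (%.1f-%.1f s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Construct a feature timecourse
#'
#' Time-stamped aperiodic parameter estimates (exponent, knee frequency,
#' R^2) for one channel; gaps are explicit `NA`s.
#'
#' @param times Time stamps in seconds.
#' @param values Named list or data.frame of per-time traces.
#' @param baseline Optional baseline metadata.
#' @return An object of class `feature_timecourse`.
#' @export
feature_timecourse <- function(times, values, baseline = NULL) {
  values <- as.data.frame(values)
  if (nrow(values) != length(times)) {
    stopf("`values` must have one row per time stamp")
  }
  structure(list(times = as.numeric(times), values = values,
                 baseline = baseline),
            class = "feature_timecourse")
}

#' @export
print.feature_timecourse <- function(x, ...) {
  cat(sprintf("<feature_timecourse> %d time points (%.1f-%.1f s): %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}
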