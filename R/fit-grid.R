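# Range/window sensitivity grid, pre-knee exponent, and time-resolved
# fitting of spectrogram slices.

#' Frequency-range sets used for sensitivity analyses
#'
#' Broad (1-30, 1-45, 1-60, 1-75 Hz), narrow (30-45, 25-45, 1-20, 1-8 Hz)
#' and moved fixed-width (1-20, 10-30, 20-40, 30-45 Hz) range sets.
#'
#' @param which `"broad"`, `"narrow"` or `"moved"`.
#' @return A list of `c(f_lo, f_hi)` ranges.
#' @export
frequency_ranges <- function(which = c("broad", "narrow", "moved")) {
  switch(match.arg(which),
         broad = list(c(1, 30), c(1, 45), c(1, 60), c(1, 75)),
         narrow = list(c(30, 45), c(25, 45), c(1, 20), c(1, 8)),
         moved = list(c(1, 20), c(10, 30), c(20, 40), c(30, 45)))
}

#' Fit a grid of frequency ranges x Welch windows
#'
#' Re-estimates the PSD of `signal` for every Welch window length and fits
#' the spectral model over every frequency range, mirroring sensitivity
#' analyses of range/window choices. Failed cells are kept with `NA`s.
#'
#' @param signal An [eeg_signal()] or numeric vector.
#' @param fs Sampling rate (ignored for `eeg_signal` input).
#' @param ranges List of `c(f_lo, f_hi)` ranges (see
#'   [frequency_ranges()]).
#' @param welch_windows Welch window lengths in seconds (default
#'   `c(5, 10, 15, 20)`).
#' @param settings Base [fit_settings()]; its `fit_range` is replaced per
#'   cell.
#' @return A [tibble::tibble] with columns `f_lo`, `f_hi`, `window_s`,
#'   `r_squared`, `exponent`, `error_mae`, `ok`.
#' @export
fit_grid <- function(signal, fs = NULL,
                     ranges = c(frequency_ranges("broad"),
                                frequency_ranges("narrow")),
                     welch_windows = c(5, 10, 15, 20),
                     settings = fit_settings()) {
  rows <- list()
  for (w in welch_windows) {
    ps <- welch_psd(signal, fs = fs, window_s = w)
    for (r in ranges) {
      s <- settings
      s$fit_range <- as.numeric(r)
      fit <- tryCatch(fit_spectral_model(ps, s), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        f_lo = r[1], f_hi = r[2], window_s = w,
        r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
        exponent = if (is.null(fit)) NA_real_ else fit_exponent(fit),
        error_mae = if (is.null(fit)) NA_real_ else fit$error_mae,
        ok = !is.null(fit))
    }
  }
  do.call(rbind, rows)
}

#' Pre-knee exponent
#'
#' The Lorentzian knee model assumes a flat spectrum below the knee; to
#' quantify how flat the sub-knee region actually is, fit a fixed
#' (single-exponent) model from 1 Hz up to the knee frequency of an
#' existing knee-mode fit.
#'
#' @param spectrum A [power_spectrum()].
#' @param knee_fit A knee-mode `spectral_fit`.
#' @param settings Base [fit_settings()] for the sub-range fit.
#' @return A fixed-mode `spectral_fit` over `[1, knee_freq]` Hz.
#' @export
pre_knee_exponent <- function(spectrum, knee_fit, settings = fit_settings()) {
  kf <- fit_knee_frequency(knee_fit)
  if (is.na(kf) || kf <= 2) {
    stopf("knee frequency must exceed 2 Hz for a pre-knee fit")
  }
  f_lo <- max(1, min(spectrum$freqs))
  n_pts <- sum(spectrum$freqs >= f_lo & spectrum$freqs <= kf)
  if (n_pts < 5L) stopf("fewer than 5 frequency points below the knee")
  s <- settings
  s$aperiodic_mode <- "fixed"
  s$fit_range <- c(f_lo, kf)
  fit_spectral_model(spectrum, s)
}

#' Time-resolved spectral parameterization
#'
#' Fits the spectral model to every time slice of a spectrogram and
#' returns exponent, knee-frequency and R^2 traces. Slices that fail to
#' fit (e.g. all-zero buffer regions) yield explicit gaps (`NA`), never
#' aborts; a trace with more than 50% failed slices is flagged.
#'
#' @param spectrogram A [spectrogram()].
#' @param settings A [fit_settings()].
#' @return A [feature_timecourse()] with value columns `exponent`,
#'   `knee_freq`, `offset`, `r_squared`; `attr(, "flagged")` is `TRUE`
#'   when more than half the slices failed.
#' @export
time_resolved_fit <- function(spectrogram, settings = fit_settings()) {
  n <- length(spectrogram$times)
  exponent <- knee_freq <- offset <- r2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- spectrogram$power[, i]
    if (any(p <= 0) || any(!is.finite(p))) next
    fit <- tryCatch(
      fit_spectral_model(list(freqs = spectrogram$freqs, powers = p),
                         settings),
      error = function(e) NULL)
    if (is.null(fit)) next
    exponent[i] <- fit_exponent(fit)
    knee_freq[i] <- fit_knee_frequency(fit)
    offset[i] <- fit$aperiodic$offset
    r2[i] <- fit$r_squared
  }
  out <- feature_timecourse(spectrogram$times,
                            list(exponent = exponent, knee_freq = knee_freq,
                                 offset = offset, r_squared = r2))
  attr(out, "flagged") <- mean(is.na(exponent)) > 0.5
  out
}
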