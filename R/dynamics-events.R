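# Event-locked analyses: time-resolved aperiodic exponent around stimuli,
# event-related potentials, K-complex candidate detection, and the
# whole-night stage-annotated report.

#' Event-locked time-resolved aperiodic exponent
#'
#' Fits the spectral model to every (decimated) time slice of each
#' trial's multitaper time-frequency decomposition, baseline-corrects the
#' per-trial exponent traces by subtracting the mean over the 500 ms
#' pre-onset window, and averages over trials. Per-slice R^2 traces are
#' retained for quality control.
#'
#' @param tfr A `trial_tfr` from [multitaper_tfr()] computed on epochs
#'   centered on the events (times relative to onset).
#' @param settings A [fit_settings()] (1-45 Hz by default).
#' @param baseline `c(t0, t1)` baseline window in seconds (default
#'   `c(-0.5, 0)`).
#' @param fit_step_s Fit one slice every `fit_step_s` seconds (default
#'   0.1).
#' @param average_trials If `TRUE`, fit the trial-averaged power per
#'   slice (one fit per time point; much lower estimator noise) instead
#'   of per-trial fits; the baseline correction then applies to the
#'   single averaged trace.
#' @return A list with `times`, `trial_exponent` (trials x times,
#'   baseline-corrected; one row when `average_trials`),
#'   `mean_exponent`, `sem` (`NA` when `average_trials`), `r_squared`
#'   (same shape as `trial_exponent`), `n_trials`.
#' @export
event_locked_exponent <- function(tfr, settings = fit_settings(),
                                  baseline = c(-0.5, 0), fit_step_s = 0.1,
                                  average_trials = FALSE) {
  stopifnot(inherits(tfr, "trial_tfr"))
  dt <- stats::median(diff(tfr$times))
  stride <- max(1L, round(fit_step_s / dt))
  sel <- seq(1L, length(tfr$times), by = stride)
  times <- tfr$times[sel]
  n_tr <- dim(tfr$power)[1]
  pw <- if (average_trials) {
    arr <- apply(tfr$power, c(2, 3), mean)
    array(arr, dim = c(1, dim(arr)))
  } else {
    tfr$power
  }
  n_fit <- dim(pw)[1]
  expo <- r2 <- matrix(NA_real_, n_fit, length(sel))
  for (tr in seq_len(n_fit)) {
    for (j in seq_along(sel)) {
      p <- pw[tr, , sel[j]]
      if (any(p <= 0) || any(!is.finite(p))) next
      fit <- tryCatch(
        fit_spectral_model(list(freqs = tfr$freqs, powers = p), settings),
        error = function(e) NULL)
      if (is.null(fit)) next
      expo[tr, j] <- fit_exponent(fit)
      r2[tr, j] <- fit$r_squared
    }
  }
  bc <- baseline_correct(expo, times, baseline_window = baseline,
                         mode = "subtract")
  m <- colMeans(bc, na.rm = TRUE)
  sem <- if (n_fit > 1) {
    apply(bc, 2L, stats::sd, na.rm = TRUE) / sqrt(n_fit)
  } else {
    rep(NA_real_, length(sel))
  }
  list(times = times, trial_exponent = bc, mean_exponent = m, sem = sem,
       r_squared = r2, n_trials = n_tr)
}

#' Event-related potential
#'
#' Relative baseline correction per trial,
#' `(data - mean baseline) / mean baseline`, followed by the grand
#' average over trials. Trials with a zero baseline mean are dropped.
#'
#' @param epochs An `epoch_set` from [epoch_and_reject()].
#' @param baseline `c(t0, t1)` in seconds relative to onset (default
#'   `c(-0.5, 0)`).
#' @param mode `"relative"` (ERP convention) or `"subtract"`.
#' @return A list with `times`, `erp` (grand-average waveform), `trials`
#'   (corrected trials x time matrix), `n_trials`.
#' @export
erp <- function(epochs, baseline = c(-0.5, 0),
                mode = c("relative", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "epoch_set"))
  mat <- epochs$epochs[epochs$kept_mask, , drop = FALSE]
  times <- (seq_len(ncol(mat)) - epochs$t_zero) / epochs$fs
  in_base <- times >= baseline[1] & times < baseline[2]
  bmean <- rowMeans(mat[, in_base, drop = FALSE])
  if (mode == "relative") {
    ok <- abs(bmean) > .Machine$double.eps
    if (any(!ok)) {
      message(sprintf("erp: dropped %d trial(s) with zero baseline mean",
                      sum(!ok)))
    }
    mat <- mat[ok, , drop = FALSE]
    bmean <- bmean[ok]
    corrected <- (mat - bmean) / bmean
  } else {
    corrected <- mat - bmean
  }
  list(times = times, erp = colMeans(corrected), trials = corrected,
       n_trials = nrow(corrected))
}

#' Detect K-complex candidates
#'
#' Scans (N2-labeled) signal for biphasic slow waves meeting the
#' candidate criteria: negative-to-positive peak-to-peak amplitude of at
#' least `min_pp_uv` (50 uV) and duration between 480 and 1500 ms. Each
#' candidate is scored by its correlation with a canonical biphasic
#' template; events with score >= `score_threshold` are returned. An
#' event is flagged `evoked` when its onset falls within 2 s after a
#' stimulus onset.
#'
#' @param signal An [eeg_signal()] or numeric vector.
#' @param fs Sampling rate (>= 100 Hz; ignored for `eeg_signal` input).
#' @param min_pp_uv Minimum peak-to-peak amplitude in uV (default 50).
#' @param dur_range_s Accepted durations in seconds (default
#'   `c(0.48, 1.5)`).
#' @param score_threshold Template-correlation threshold (default 0.8).
#' @param stim_onsets Optional stimulus onsets (s) for the evoked flag.
#' @param channel Channel for multi-channel input.
#' @return A [tibble::tibble] with columns `onset_s`, `p2p_uv`,
#'   `duration_s`, `score`, `evoked`.
#' @export
kc_detect <- function(signal, fs = NULL, min_pp_uv = 50,
                      dur_range_s = c(0.48, 1.5), score_threshold = 0.8,
                      stim_onsets = NULL, channel = 1L) {
  if (inherits(signal, "eeg_signal")) {
    fs <- signal$fs
    x <- signal_channel(signal, channel)
  } else {
    if (is.null(fs)) stopf("`fs` required for plain numeric input")
    x <- as.numeric(signal)
  }
  if (fs < 100) stopf("`fs` must be >= 100 Hz for K-complex detection")
  # slow-wave band emphasizes the biphasic morphology
  bf <- signal::butter(2, c(0.5, 4) / (fs / 2), type = "pass")
  xl <- signal::filtfilt(bf, x)
  n <- length(xl)
  # candidate negative peaks: local minima below -min_pp_uv/4
  is_min <- c(FALSE, diff(sign(diff(xl))) > 0, FALSE) &
    xl < -min_pp_uv / 4
  cand <- which(is_min)
  empty <- tibble::tibble(onset_s = numeric(0), p2p_uv = numeric(0),
                          duration_s = numeric(0), score = numeric(0),
                          evoked = logical(0))
  if (!length(cand)) return(empty)
  rows <- list()
  last_end <- 0
  for (i0 in cand) {
    if (i0 <= last_end) next  # avoid overlapping detections
    # following positive peak within the maximum duration
    horizon <- min(n, i0 + round(dur_range_s[2] * fs))
    seg <- xl[i0:horizon]
    i1 <- i0 + which.max(seg) - 1L
    if (i1 <= i0) next
    p2p <- xl[i1] - xl[i0]
    # onset: last downward zero crossing before the trough; end: first
    # zero crossing after the positive peak
    pre <- which(xl[seq_len(i0)] >= 0)
    on_i <- if (length(pre)) max(pre) else 1L
    post <- which(xl[i1:n] <= 0)
    end_i <- if (length(post)) i1 + min(post) - 1L else n
    dur <- (end_i - on_i) / fs
    if (p2p < min_pp_uv || dur < dur_range_s[1] || dur > dur_range_s[2]) {
      next
    }
    wave <- xl[on_i:end_i]
    tmpl <- kc_waveform(length(wave), 1, 2)  # unit canonical shape
    score <- suppressWarnings(stats::cor(wave, tmpl))
    if (!is.finite(score) || score < score_threshold) next
    last_end <- end_i
    rows[[length(rows) + 1L]] <- tibble::tibble(
      onset_s = (on_i - 1) / fs, p2p_uv = p2p, duration_s = dur,
      score = score, evoked = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(stim_onsets) && length(stim_onsets)) {
    out$evoked <- vapply(out$onset_s, function(t0) {
      any(t0 - stim_onsets >= 0 & t0 - stim_onsets <= 2)
    }, logical(1))
  }
  out
}

#' Whole-night stage-annotated aperiodic report
#'
#' Computes one spectral fit per 30-s epoch (Welch PSD within the epoch,
#' then [fit_spectral_model()]) with the epoch's stage label attached;
#' the output feeds [quartile_course()] and [epoch_regression()].
#'
#' @param signal An [eeg_signal()].
#' @param hyp The matching [hypnogram()].
#' @param settings A [fit_settings()].
#' @param welch_window_s Welch window within each epoch (default 10 s so
#'   a 30-s epoch yields averaged segments).
#' @param channel Channel for multi-channel input.
#' @return A [tibble::tibble] with one row per epoch: `epoch`, `stage`,
#'   `onset_s`, `offset`, `exponent`, `knee_freq`, `r_squared`.
#' @export
whole_night_report <- function(signal, hyp, settings = fit_settings(),
                               welch_window_s = 10, channel = 1L) {
  stopifnot(inherits(signal, "eeg_signal"), inherits(hyp, "hypnogram"))
  fs <- signal$fs
  x <- signal_channel(signal, channel)
  L <- round(hyp$epoch_s * fs)
  n_ep <- min(length(hyp$stages), floor(length(x) / L))
  rows <- lapply(seq_len(n_ep), function(i) {
    seg <- x[((i - 1L) * L + 1L):(i * L)]
    fit <- tryCatch({
      ps <- welch_psd(seg, fs = fs, window_s = welch_window_s)
      fit_spectral_model(ps, settings)
    }, error = function(e) NULL)
    tibble::tibble(
      epoch = i, stage = hyp$stages[i], onset_s = epoch_onset(hyp, i),
      offset = if (is.null(fit)) NA_real_ else fit$aperiodic$offset,
      exponent = if (is.null(fit)) NA_real_ else fit_exponent(fit),
      knee_freq = if (is.null(fit)) NA_real_ else fit_knee_frequency(fit),
      r_squared = if (is.null(fit)) NA_real_ else fit$r_squared)
  })
  do.call(rbind, rows)
}
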