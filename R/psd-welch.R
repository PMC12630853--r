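# Welch PSD estimation: Hamming-tapered, constant-detrended segments with
# 50% overlap, one-sided density scaling (uV^2/Hz). Frequency resolution
# is 1/window_s.

# One-sided Welch PSD of a numeric vector. Returns list(freqs, psd).
welch_vector <- function(x, fs, window_s, overlap_frac) {
  w <- round(window_s * fs)
  if (length(x) < w) stopf("signal shorter than one Welch window")
  step <- max(1L, round(w * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - w + 1L, by = step)
  taper <- signal::hamming(w)
  u <- sum(taper^2)
  nf <- floor(w / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + w - 1L)]
    seg <- (seg - mean(seg)) * taper
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2 / (fs * u)
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when w is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (w %% 2 == 0) dbl[nf] <- 1
  list(freqs = (seq_len(nf) - 1) * fs / w, psd = psd * dbl)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with Hamming taper, constant detrend per
#' segment, and 50% overlap by default (15-s windows, giving a frequency
#' step of 1/15 Hz).
#'
#' @param signal An [eeg_signal()] or numeric vector.
#' @param fs Sampling rate in Hz (ignored when `signal` is an
#'   `eeg_signal`).
#' @param window_s Segment length in seconds (default 15).
#' @param overlap_frac Fractional overlap between segments (default 0.5).
#' @return A [power_spectrum()]; multi-channel input yields a matrix of
#'   powers with one column per channel.
#' @export
welch_psd <- function(signal, fs = NULL, window_s = 15, overlap_frac = 0.5) {
  check_number(window_s, "window_s", lower = .Machine$double.eps)
  check_number(overlap_frac, "overlap_frac", lower = 0, upper = 0.99)
  if (inherits(signal, "eeg_signal")) {
    fs <- signal$fs
    mat <- signal$samples
  } else {
    if (is.null(fs)) stopf("`fs` required for plain numeric input")
    mat <- matrix(as.numeric(signal), nrow = 1L)
  }
  res <- apply(mat, 1L, welch_vector, fs = fs, window_s = window_s,
               overlap_frac = overlap_frac, simplify = FALSE)
  freqs <- res[[1]]$freqs
  powers <- vapply(res, `[[`, numeric(length(freqs)), "psd")
  if (ncol(powers) == 1L) powers <- powers[, 1L]
  power_spectrum(freqs, powers,
                 settings = list(method = "welch", fs = fs,
                                 window_s = window_s,
                                 overlap_frac = overlap_frac))
}

#' Sliding-window PSD (spectrogram)
#'
#' Segments the signal into `window_s`-long intervals advanced by `step_s`
#' (defaults 20 s / 2 s, i.e. 90% overlap) and computes one Welch PSD per
#' window. Window time stamps are window *centers*.
#'
#' @param signal An [eeg_signal()] or numeric vector.
#' @param fs Sampling rate (ignored for `eeg_signal` input).
#' @param window_s Interval length in seconds (default 20).
#' @param step_s Interval step in seconds (default 2).
#' @param welch_window_s Welch segment length within each interval
#'   (default 15 s, truncated to the interval if longer).
#' @param channel Channel index or label for multi-channel input.
#' @return A [spectrogram()].
#' @export
sliding_psd <- function(signal, fs = NULL, window_s = 20, step_s = 2,
                        welch_window_s = 15, channel = 1L) {
  if (step_s <= 0) stopf("`step_s` must be positive")
  if (inherits(signal, "eeg_signal")) {
    fs <- signal$fs
    x <- signal_channel(signal, channel)
  } else {
    if (is.null(fs)) stopf("`fs` required for plain numeric input")
    x <- as.numeric(signal)
  }
  w <- round(window_s * fs)
  if (length(x) < w) stopf("signal shorter than one window")
  step <- round(step_s * fs)
  starts <- seq(1L, length(x) - w + 1L, by = step)
  ww <- min(welch_window_s, window_s)
  cols <- lapply(starts, function(s) {
    welch_vector(x[s:(s + w - 1L)], fs, ww, 0.5)
  })
  freqs <- cols[[1]]$freqs
  power <- vapply(cols, `[[`, numeric(length(freqs)), "psd")
  times <- (starts - 1) / fs + window_s / 2
  spectrogram(times, freqs, power,
              settings = list(method = "sliding_welch", fs = fs,
                              window_s = window_s, step_s = step_s,
                              welch_window_s = ww))
}
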