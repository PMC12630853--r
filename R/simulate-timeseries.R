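# Aperiodic time-series generator: shapes white noise in the frequency
# domain so that the expected one-sided PSD is proportional to
# 1/(k + f^x), with uniformly random phases. Used to exercise PSD
# estimation and spectral fitting end to end.

#' Simulate an aperiodic (1/f-like) time series
#'
#' Draws complex spectral amplitudes with magnitude
#' `sqrt(1/(k + f^x))` (where `k = knee_freq^x`, 0 if no knee) and uniform
#' random phases, and inverse-transforms to a real signal. The output is
#' rescaled to the requested standard deviation.
#'
#' @param exponent Aperiodic exponent x (>= 0; 0 with no knee gives white
#'   noise).
#' @param knee_freq Knee frequency in Hz, or `NULL` for a pure power law.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param scale_uv Target standard deviation of the output in microvolts
#'   (default 20).
#' @param seed Integer seed or `NULL`.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
simulate_aperiodic_timeseries <- function(exponent, knee_freq = NULL,
                                          duration_s, fs, scale_uv = 20,
                                          seed = NULL) {
  check_number(exponent, "exponent", lower = 0)
  check_number(duration_s, "duration_s", lower = .Machine$double.eps)
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (!is.null(knee_freq)) {
    check_number(knee_freq, "knee_freq", lower = 0)
    if (knee_freq > fs / 2) {
      stopf("`fs` too low to represent knee frequency %g Hz", knee_freq)
    }
  }
  n <- round(duration_s * fs)
  if (n < 2L) stopf("signal too short")
  k <- if (is.null(knee_freq)) 0 else knee_freq^exponent
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
  mag <- numeric(length(freqs))
  pos <- freqs > 0
  mag[pos] <- sqrt(1 / (k + freqs[pos]^exponent))
  if (k > 0) mag[1] <- sqrt(1 / k)
  x <- with_seed(seed, {
    # shape complex Gaussian white noise by the target magnitude profile
    # (uniform random phases, Rayleigh amplitudes)
    half <- mag * (stats::rnorm(length(freqs)) +
                     1i * stats::rnorm(length(freqs))) / sqrt(2)
    half[1] <- 0  # zero mean
    # Assemble the full Hermitian spectrum for a real-valued signal.
    if (n %% 2 == 0) {
      half[length(half)] <- Re(half[length(half)])
      full <- c(half, Conj(rev(half[2:(length(half) - 1L)])))
    } else {
      full <- c(half, Conj(rev(half[2:length(half)])))
    }
    Re(stats::fft(full, inverse = TRUE)) / n
  })
  s <- stats::sd(x)
  if (s > 0) x <- x * (scale_uv / s)
  x
}
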