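# DPSS multitaper time-frequency decomposition. Tapers are computed from
# the symmetric tridiagonal formulation of the Slepian concentration
# problem (Percival & Walden); with the number of cycles set equal to each
# frequency, the analysis window is 1 s at every frequency, so a single
# taper family of length fs suffices.

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix of unit-norm tapers, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  n <- as.integer(n)
  if (n < 2L) stopf("taper length must be >= 2")
  w <- nw / n
  i <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1L) * (n - seq_len(n - 1L))) / 2
  m <- diag(diag_main)
  m[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  m[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(m, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers have positive mean, antisymmetric
  # tapers a positive initial lobe
  for (j in seq_len(k)) {
    s <- if (abs(sum(tapers[, j])) > 1e-8) sign(sum(tapers[, j])) else
      sign(tapers[2L, j] - tapers[1L, j])
    tapers[, j] <- tapers[, j] * s
  }
  tapers
}

# FFT-based 'same' convolution of a real vector with a complex kernel.
conv_same <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  nfft <- stats::nextn(n + m - 1L, 2L)
  res <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                      stats::fft(c(kern, rep(0, nfft - m))), inverse = TRUE) /
    nfft
  start <- floor(m / 2)
  res[(start + 1L):(start + n)]
}

#' Multitaper time-frequency decomposition of epoched data
#'
#' Convolution with DPSS-tapered complex exponentials on a 1-45 Hz grid in
#' 0.5 Hz steps by default, with the number of cycles equal to each
#' frequency so the analysis window is 1 s throughout. The first and last
#' second of each epoch are discarded to avoid edge artifacts.
#'
#' @param epochs An `epoch_set` (see [epoch_and_reject()]) or a
#'   trials-by-time numeric matrix.
#' @param fs Sampling rate (ignored for `epoch_set` input).
#' @param f_min,f_max,f_step Frequency grid in Hz (defaults 1, 45, 0.5).
#' @param nw Time-bandwidth product for the tapers (default 2, giving 3
#'   tapers).
#' @param decim Temporal decimation factor of the output (default 1).
#' @return A list of class `trial_tfr`: `times` (s, relative to epoch
#'   start of the retained span), `freqs`, and `power`, an array
#'   `[trials, freqs, times]` of linear power. Rejected trials of an
#'   `epoch_set` are dropped.
#' @export
multitaper_tfr <- function(epochs, fs = NULL, f_min = 1, f_max = 45,
                           f_step = 0.5, nw = 2, decim = 1L) {
  if (inherits(epochs, "epoch_set")) {
    fs <- epochs$fs
    mat <- epochs$epochs[epochs$kept_mask, , drop = FALSE]
    t0 <- epochs$t_zero
  } else {
    if (is.null(fs)) stopf("`fs` required for matrix input")
    mat <- as.matrix(epochs)
    t0 <- NA_integer_
  }
  n_time <- ncol(mat)
  if (n_time <= 2 * fs) stopf("epochs must be longer than 2 s for trimming")
  win <- round(fs)  # 1 s at every frequency (n_cycles = frequency)
  tapers <- dpss_tapers(win, nw = nw)
  freqs <- seq(f_min, f_max, by = f_step)
  tt <- (seq_len(win) - (win + 1) / 2) / fs
  keep <- seq(round(fs) + 1L, n_time - round(fs))
  keep <- keep[seq(1L, length(keep), by = decim)]
  out <- array(0, dim = c(nrow(mat), length(freqs), length(keep)))
  for (fi in seq_along(freqs)) {
    carrier <- exp(1i * 2 * pi * freqs[fi] * tt)
    kerns <- lapply(seq_len(ncol(tapers)),
                    function(j) tapers[, j] * carrier)
    for (tr in seq_len(nrow(mat))) {
      p <- 0
      for (kern in kerns) {
        p <- p + abs(conv_same(mat[tr, ], kern))^2
      }
      out[tr, fi, ] <- (p / ncol(tapers) * 2 / fs)[keep]
    }
  }
  times <- (keep - 1) / fs
  if (!is.na(t0)) times <- times - (t0 - 1) / fs
  structure(list(times = times, freqs = freqs, power = out,
                 settings = list(fs = fs, nw = nw,
                                 n_tapers = ncol(tapers), decim = decim)),
            class = "trial_tfr")
}

# Average a trial TFR over trials and time -> power_spectrum (used to
# compare against Welch on stationary signals).
tfr_mean_spectrum <- function(tfr) {
  power_spectrum(tfr$freqs, apply(tfr$power, 2L, mean),
                 settings = list(method = "multitaper_mean"))
}
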