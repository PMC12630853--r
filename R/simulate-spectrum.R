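# Synthetic power spectra: the generator mirrors the model class that the
# fitting routines assume, i.e. log10 power = offset - log10(knee + f^x)
# plus Gaussian oscillatory peaks in log10 power, plus i.i.d. Gaussian
# log10-power noise.

#' Specify a simulated power spectrum
#'
#' The knee is supplied as a knee *frequency* in Hz (the interpretable
#' quantity) and converted internally to the knee constant
#' `k = knee_freq^exponent`. Peak bandwidth follows the convention
#' bandwidth = 2 * (Gaussian sd).
#'
#' @param f_range Frequency range `c(f_min, f_max)` in Hz, `f_min > 0`.
#' @param f_step Frequency step in Hz.
#' @param mode `"fixed"` (pure power law) or `"knee"` (Lorentzian bend).
#' @param offset Aperiodic offset b in log10-power units.
#' @param knee_freq Knee frequency in Hz (knee mode only).
#' @param exponent Aperiodic exponent x (> 0).
#' @param peaks List of length-3 vectors `c(center_hz, height_log10,
#'   bandwidth_hz)`, or `NULL` for none.
#' @param noise_sd Standard deviation of additive log10-power noise
#'   (default 0.05).
#' @param seed Integer seed for the noise, or `NULL`.
#' @return A list of class `sim_spectrum_spec`.
#' @export
sim_spectrum_spec <- function(f_range = c(1, 45), f_step = 0.25,
                              mode = c("knee", "fixed"),
                              offset = 1, knee_freq = NULL, exponent = 1,
                              peaks = NULL, noise_sd = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (length(f_range) != 2L || f_range[1] <= 0 || f_range[2] <= f_range[1]) {
    stopf("`f_range` must be c(f_min, f_max) with 0 < f_min < f_max")
  }
  check_number(f_step, "f_step", lower = .Machine$double.eps)
  check_number(exponent, "exponent", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (mode == "knee") {
    check_number(knee_freq, "knee_freq", lower = 0)
  } else if (!is.null(knee_freq)) {
    stopf("`knee_freq` must be absent in fixed mode")
  }
  if (!is.null(peaks)) {
    peaks <- lapply(peaks, function(p) {
      if (length(p) != 3L || any(!is.finite(p)) || p[3] <= 0) {
        stopf("each peak must be c(center_hz, height, bandwidth_hz)")
      }
      as.numeric(p)
    })
  }
  structure(list(f_range = as.numeric(f_range), f_step = f_step, mode = mode,
                 offset = offset, knee_freq = knee_freq, exponent = exponent,
                 peaks = peaks, noise_sd = noise_sd, seed = seed),
            class = "sim_spectrum_spec")
}

# Sum of Gaussian peaks evaluated in log10-power; bandwidth = 2*sd.
peak_log_power <- function(freqs, peaks) {
  out <- numeric(length(freqs))
  for (p in peaks) {
    sd <- p[3] / 2
    out <- out + p[2] * exp(-(freqs - p[1])^2 / (2 * sd^2))
  }
  out
}

#' Simulate a power spectrum
#'
#' Generates log10 power as `offset - log10(k + f^x)` (with `k = 0` in
#' fixed mode, `k = knee_freq^x` in knee mode), adds Gaussian peaks and
#' i.i.d. Gaussian noise in log10 power, and returns the spectrum in
#' linear power. Reproducible under a fixed seed.
#'
#' @param spec A [sim_spectrum_spec()].
#' @return A [power_spectrum()].
#' @examples
#' spec <- sim_spectrum_spec(mode = "knee", offset = 1.5, knee_freq = 13.13,
#'                           exponent = 1.25,
#'                           peaks = list(c(10, 0.9, 2.5), c(30, 0.6, 5)),
#'                           noise_sd = 0.05, seed = 1)
#' ps <- simulate_power_spectrum(spec)
#' @export
simulate_power_spectrum <- function(spec) {
  stopifnot(inherits(spec, "sim_spectrum_spec"))
  freqs <- seq(spec$f_range[1], spec$f_range[2], by = spec$f_step)
  k <- if (spec$mode == "knee") spec$knee_freq^spec$exponent else 0
  log_p <- spec$offset - log10(k + freqs^spec$exponent)
  if (!is.null(spec$peaks)) {
    log_p <- log_p + peak_log_power(freqs, spec$peaks)
  }
  if (spec$noise_sd > 0) {
    log_p <- log_p + with_seed(spec$seed,
                               stats::rnorm(length(freqs), 0, spec$noise_sd))
  }
  power_spectrum(freqs, 10^log_p,
                 settings = list(source = "simulate_power_spectrum",
                                 spec = spec))
}
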