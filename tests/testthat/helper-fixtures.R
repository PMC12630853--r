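# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The worked-example spectrum: knee at 13.13 Hz, exponent 1.25, peaks at
# 10 and 30 Hz, on 1-45 Hz.
fig_spectrum_spec <- function(noise_sd = 0.05, seed = 1, f_range = c(1, 45)) {
  sim_spectrum_spec(f_range = f_range, mode = "knee", offset = 1.5,
                    knee_freq = 13.13, exponent = 1.25,
                    peaks = list(c(10, 0.9, 2.5), c(30, 0.6, 5)),
                    noise_sd = noise_sd, seed = seed)
}

# Event-free, K-complex-free night (stage backgrounds only).
quiet_recording_spec <- function(n_epochs, seed, ...) {
  sim_recording_spec(
    fs = 200, n_epochs = n_epochs, initial_stage = "N1", seed = seed,
    event_response = list(shift = 0, latency_s = 0, duration_s = 0,
                          prob = 0),
    kc_params = list(p2p_uv = 0, duration_s = 0.9, rate_per_min = 0,
                     evoked_prob = 0), ...)
}

# Stage-averaged Welch PSD for one stage of a recording.
stage_mean_psd <- function(rec, stage, welch_window_s = 10) {
  fs <- rec$signal$fs
  x <- rec$signal$samples[1, ]
  L <- round(rec$hypnogram$epoch_s * fs)
  eps <- which(rec$hypnogram$stages == stage)
  acc <- NULL
  for (i in eps) {
    ps <- welch_psd(x[((i - 1) * L + 1):(i * L)], fs = fs,
                    window_s = welch_window_s)
    acc <- if (is.null(acc)) ps$powers else acc + ps$powers
  }
  power_spectrum(ps$freqs, acc / length(eps))
}

true_stage_exponents <- c(Wake = 1.0, N1 = 1.3, N2 = 1.6, N3 = 2.0,
                          REM = 1.2)

# Shared quiet night used by several stage-level tests.
quiet_night <- function() {
  cached("quiet_night", function() {
    rec <- simulate_sleep_recording(quiet_recording_spec(150, seed = 42))
    report <- whole_night_report(
      rec$signal, rec$hypnogram,
      fit_settings(aperiodic_mode = "fixed", max_n_peaks = 2))
    list(rec = rec, report = report)
  })
}

# Brute-force Friedman chi-square and Kendall W from first principles
# (midranks within rows).
brute_friedman <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  # tie-corrected Friedman statistic (matches stats::friedman.test)
  tie_term <- sum(apply(m, 1, function(r) {
    tab <- table(r)
    sum(tab^3 - tab)
  }))
  num <- 12 * sum((rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tie_term / (k - 1)
  x2 <- num / den
  list(x2 = x2, w = x2 / (n * (k - 1)))
}

# Brute-force Cliff's delta by pair enumeration (ties count 0.5).
brute_cliffs <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  2 * s / (length(a) * length(b)) - 1
}
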