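# Synthetic sleep-recording generator: a Markovian hypnogram drives
# stage-specific aperiodic parameters and oscillations; auditory stimuli
# are laid out in stimulation/quiet blocks with jittered inter-stimulus
# intervals, optionally followed by transient exponent shifts and
# K-complex-like biphasic waveforms. This provides ground truth for every
# downstream analysis stage without any external data.

#' Default stage-specific aperiodic parameters and oscillations
#'
#' Scalp-EEG-like defaults: exponents deepen from Wake (1.0) to N3 (2.0)
#' and drop in REM (1.2); knee frequencies are lowest in N3; each stage
#' carries a characteristic oscillation (alpha, theta, spindle band,
#' slow activity).
#'
#' @return Named list per stage of `list(exponent, knee_freq,
#'   oscillations)`.
#' @export
default_stage_params <- function() {
  list(
    Wake = list(exponent = 1.0, knee_freq = 10,
                oscillations = list(c(10, 0.5))),
    N1 = list(exponent = 1.3, knee_freq = 8,
              oscillations = list(c(7, 0.3))),
    N2 = list(exponent = 1.6, knee_freq = 6,
              oscillations = list(c(13, 0.5))),
    N3 = list(exponent = 2.0, knee_freq = 2.5,
              oscillations = list(c(0.8, 0.6))),
    REM = list(exponent = 1.2, knee_freq = 9,
               oscillations = list(c(5, 0.2)))
  )
}

#' Default sleep-stage transition matrix
#'
#' Row-stochastic per-epoch (30 s) transition probabilities over
#' Wake/N1/N2/N3/REM with plausible sleep-architecture persistence.
#'
#' @return A 5x5 matrix with rows summing to 1.
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    Wake = c(0.90, 0.08, 0.02, 0.00, 0.00),
    N1   = c(0.05, 0.70, 0.23, 0.00, 0.02),
    N2   = c(0.01, 0.05, 0.85, 0.06, 0.03),
    N3   = c(0.00, 0.00, 0.10, 0.88, 0.02),
    REM  = c(0.02, 0.03, 0.05, 0.00, 0.90)
  )
  colnames(m) <- sleep_stages()
  m
}

#' Specify a simulated sleep recording
#'
#' Defaults emulate a scalp-EEG night: stage exponents deepen from Wake
#' (1.0) through N3 (2.0) and drop in REM (1.2), knee frequencies are
#' lowest in N3, and each stage carries a characteristic oscillation
#' (alpha in Wake, spindle-band in N2, slow activity in N3). Auditory
#' stimulation alternates 90-min stimulation with 30-min quiet blocks and
#' inter-stimulus intervals are jittered between 2800 and 7800 ms in
#' 500 ms steps.
#'
#' @param fs Sampling rate in Hz (default 200).
#' @param n_epochs Number of 30-s epochs.
#' @param epoch_s Epoch length in seconds (default 30).
#' @param stage_params Named list (per stage) of
#'   `list(exponent, knee_freq, oscillations)`; `oscillations` is a list of
#'   `c(freq_hz, relative_amplitude)`.
#' @param transition_matrix 5x5 row-stochastic stage transition matrix
#'   (rows/cols Wake, N1, N2, N3, REM).
#' @param stim_minutes,quiet_minutes,n_cycles Stimulation block structure
#'   (defaults 90, 30, 4); blocks are truncated to the recording length.
#' @param isi_ms Allowed inter-stimulus intervals in ms (default
#'   `seq(2800, 7800, by = 500)`).
#' @param event_response `list(shift, latency_s, duration_s, prob)`: each
#'   stimulus is followed, with probability `prob`, by a transient
#'   aperiodic-exponent shift of magnitude `shift` starting `latency_s`
#'   after onset and lasting `duration_s`. Use `shift = 0` to disable.
#' @param kc_params `list(p2p_uv, duration_s, rate_per_min, evoked_prob)`:
#'   K-complex-like biphasic waveforms injected in N2 (spontaneous at
#'   `rate_per_min`; after each N2 stimulus with probability
#'   `evoked_prob`). Use `rate_per_min = 0` and `evoked_prob = 0` to
#'   disable.
#' @param scale_uv Per-epoch signal standard deviation in microvolts.
#' @param initial_stage Stage of the first hypnogram epoch (default
#'   `"Wake"`).
#' @param seed Integer master seed; fans out deterministically to all
#'   stage-local draws.
#' @return A list of class `sim_recording_spec`.
#' @export
sim_recording_spec <- function(fs = 200, n_epochs = 40, epoch_s = 30,
                               stage_params = default_stage_params(),
                               transition_matrix = default_transition_matrix(),
                               stim_minutes = 90, quiet_minutes = 30,
                               n_cycles = 4,
                               isi_ms = seq(2800, 7800, by = 500),
                               event_response = list(shift = 0.4,
                                                     latency_s = 0.1,
                                                     duration_s = 0.8,
                                                     prob = 1),
                               kc_params = list(p2p_uv = 150,
                                                duration_s = 0.9,
                                                rate_per_min = 1,
                                                evoked_prob = 0.25),
                               scale_uv = 20, initial_stage = "Wake",
                               seed = 1) {
  check_number(fs, "fs", lower = 50)
  check_number(n_epochs, "n_epochs", lower = 1)
  check_number(epoch_s, "epoch_s", lower = 1)
  if (!all(abs(rowSums(transition_matrix) - 1) < 1e-8)) {
    stopf("rows of `transition_matrix` must sum to 1")
  }
  if (any(isi_ms <= 0)) stopf("`isi_ms` must be positive")
  structure(list(fs = fs, n_epochs = as.integer(n_epochs), epoch_s = epoch_s,
                 stage_params = stage_params,
                 transition_matrix = transition_matrix,
                 stim_minutes = stim_minutes, quiet_minutes = quiet_minutes,
                 n_cycles = n_cycles, isi_ms = isi_ms,
                 event_response = event_response, kc_params = kc_params,
                 scale_uv = scale_uv, initial_stage = initial_stage,
                 seed = seed),
            class = "sim_recording_spec")
}

#' Simulate a Markovian hypnogram
#'
#' @param n_epochs Number of epochs.
#' @param transition_matrix Row-stochastic 5x5 matrix over
#'   Wake/N1/N2/N3/REM.
#' @param epoch_s Epoch duration in seconds.
#' @param initial Initial stage label.
#' @param seed Integer seed.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(n_epochs,
                               transition_matrix = default_transition_matrix(),
                               epoch_s = 30, initial = "Wake", seed = NULL) {
  stages <- sleep_stages()
  if (!all(abs(rowSums(transition_matrix) - 1) < 1e-8)) {
    stopf("rows of `transition_matrix` must sum to 1")
  }
  labels <- with_seed(seed, {
    out <- character(n_epochs)
    cur <- match(canonical_stage(initial), stages)
    for (i in seq_len(n_epochs)) {
      out[i] <- stages[cur]
      cur <- sample.int(5L, 1L, prob = transition_matrix[cur, ])
    }
    out
  })
  hypnogram(labels, epoch_s = epoch_s)
}

# Canonical biphasic K-complex-like waveform: negative then positive
# half-wave, peak-to-peak amplitude p2p_uv over duration_s.
kc_waveform <- function(fs, duration_s = 0.9, p2p_uv = 150) {
  n <- round(duration_s * fs)
  t <- seq(0, duration_s, length.out = n)
  -(p2p_uv / 2) * sin(2 * pi * t / duration_s)
}

# Stimulus onsets inside stimulation blocks, with jittered ISIs.
# Returns onsets in seconds; all onsets lie inside [block_start, block_end).
sim_stim_onsets <- function(duration_s, stim_minutes, quiet_minutes, n_cycles,
                            isi_s, seed) {
  cycle_s <- (stim_minutes + quiet_minutes) * 60
  stim_s <- stim_minutes * 60
  with_seed(seed, {
    onsets <- numeric(0)
    for (cyc in seq_len(n_cycles)) {
      b0 <- (cyc - 1) * cycle_s
      if (b0 >= duration_s) break
      b1 <- min(b0 + stim_s, duration_s)
      t <- b0 + sample(isi_s, 1L)
      while (t < b1 - 2) {  # keep a margin so responses fit in the block
        onsets <- c(onsets, t)
        t <- t + sample(isi_s, 1L)
      }
    }
    onsets
  })
}

# One epoch of stage-specific signal: 1/f background plus band-limited
# oscillations (narrowband-filtered noise, ~2 Hz bandwidth, so spectral
# peaks are Gaussian-like and within the model's peak-width limits),
# amplitude-modulated at 50% depth with smooth onsets/offsets.
sim_stage_epoch <- function(params, n, fs, scale_uv, seed) {
  x <- simulate_aperiodic_timeseries(params$exponent, params$knee_freq,
                                     n / fs, fs, scale_uv = scale_uv,
                                     seed = seed)
  if (length(params$oscillations)) {
    t <- seq_len(n) / fs
    osc_seed <- if (is.null(seed)) NULL else seed - 1L
    oscs <- with_seed(osc_seed, {
      o <- numeric(n)
      for (osc in params$oscillations) {
        half_bw <- max(0.5, 0.1 * osc[1])
        band <- c(max(0.05, osc[1] - half_bw), min(fs / 2 - 1e-3,
                                                   osc[1] + half_bw))
        bf <- signal::butter(2, band / (fs / 2), type = "pass")
        nb <- signal::filtfilt(bf, stats::rnorm(n))
        nb <- nb / stats::sd(nb)
        phi <- stats::runif(1, 0, 2 * pi)
        # 50% modulation depth: envelope in [0.5, 1] x base amplitude
        env <- 0.75 + 0.25 * sin(2 * pi * 0.4 * t + phi)
        o <- o + osc[2] * scale_uv * env * nb
      }
      # smooth onset/offset over 0.25 s against edge leakage
      nr <- min(round(0.25 * fs), floor(n / 2))
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      o[seq_len(nr)] <- o[seq_len(nr)] * ramp
      o[(n - nr + 1):n] <- o[(n - nr + 1):n] * rev(ramp)
      o
    })
    x <- x + oscs
  }
  x
}

#' Simulate a sleep recording
#'
#' Concatenates per-epoch stage-specific segments (cross-faded over 0.5 s
#' at epoch boundaries), lays out stimulus events inside stimulation
#' blocks, and injects the configured transient exponent shifts and
#' K-complex waveforms.
#'
#' @param spec A [sim_recording_spec()].
#' @return A list with elements `signal` ([eeg_signal()]), `hypnogram`
#'   ([hypnogram()]), `events` (stimulus [event_table()] with categories
#'   from \{SON, UN\} x \{FV, UFV\}), and `kcs` (onsets of injected
#'   K-complex waveforms, with an `evoked` column).
#' @export
simulate_sleep_recording <- function(spec) {
  stopifnot(inherits(spec, "sim_recording_spec"))
  fs <- spec$fs
  L <- round(spec$epoch_s * fs)
  n_total <- L * spec$n_epochs
  duration_s <- n_total / fs
  seeds <- seed_stream(spec$seed, spec$n_epochs + 6L)

  hyp <- simulate_hypnogram(spec$n_epochs, spec$transition_matrix,
                            epoch_s = spec$epoch_s,
                            initial = spec$initial_stage, seed = seeds[[1]])
  missing <- setdiff(unique(hyp$stages), names(spec$stage_params))
  if (length(missing)) {
    stopf("`stage_params` missing for stage(s): %s",
          paste(missing, collapse = ", "))
  }

  # --- background: per-epoch segments, overlap-added with 0.5 s crossfade
  xf <- round(0.5 * fs)
  sig <- numeric(n_total + xf)
  ramp_up <- 0.5 * (1 - cos(pi * seq_len(xf) / xf))
  for (i in seq_len(spec$n_epochs)) {
    p <- spec$stage_params[[hyp$stages[i]]]
    len <- if (i < spec$n_epochs) L + xf else L
    seg <- sim_stage_epoch(p, len, fs, spec$scale_uv, seeds[[i + 1L]])
    w <- rep(1, len)
    if (i > 1L) w[seq_len(xf)] <- ramp_up
    if (i < spec$n_epochs) w[(len - xf + 1):len] <- rev(ramp_up)
    idx <- ((i - 1L) * L + 1L):((i - 1L) * L + len)
    sig[idx] <- sig[idx] + seg * w
  }
  sig <- sig[seq_len(n_total)]

  # --- stimulus events inside stimulation blocks
  onsets <- sim_stim_onsets(duration_s, spec$stim_minutes,
                            spec$quiet_minutes, spec$n_cycles,
                            spec$isi_ms / 1000,
                            seeds[[spec$n_epochs + 2L]])
  cats <- with_seed(seeds[[spec$n_epochs + 3L]], {
    paste(sample(c("SON", "UN"), length(onsets), replace = TRUE),
          sample(c("FV", "UFV"), length(onsets), replace = TRUE),
          sep = "_")
  })
  events <- event_table(onsets, cats)

  stage_at <- function(t) hyp$stages[pmin(floor(t / spec$epoch_s) + 1L,
                                          spec$n_epochs)]

  # --- transient event-locked exponent shifts
  er <- spec$event_response
  if (length(onsets) && er$shift != 0 && er$prob > 0) {
    ev_seeds <- seed_stream(seeds[[spec$n_epochs + 4L]],
                            max(1L, length(onsets)))
    rr <- round(0.1 * fs)  # 0.1 s crossfade into/out of the shifted segment
    rmp <- 0.5 * (1 - cos(pi * seq_len(rr) / rr))
    for (j in seq_along(onsets)) {
      apply_j <- with_seed(ev_seeds[[j]], stats::runif(1)) <= er$prob
      if (!apply_j) next
      st <- spec$stage_params[[stage_at(onsets[j])]]
      i0 <- round((onsets[j] + er$latency_s) * fs) + 1L
      i1 <- min(i0 + round(er$duration_s * fs) - 1L, n_total)
      if (i1 - i0 < 2 * rr) next
      seg <- sig[i0:i1]
      rep_seg <- simulate_aperiodic_timeseries(
        st$exponent + er$shift, st$knee_freq, (i1 - i0 + 1L) / fs, fs,
        scale_uv = max(stats::sd(seg), 1e-6), seed = ev_seeds[[j]])
      w <- rep(1, length(seg))
      w[seq_len(rr)] <- rmp
      w[(length(seg) - rr + 1):length(seg)] <- rev(rmp)
      sig[i0:i1] <- seg * (1 - w) + rep_seg * w
    }
  }

  # --- K-complex-like waveforms in N2
  kc <- spec$kc_params
  kc_onsets <- numeric(0)
  kc_evoked <- logical(0)
  if (kc$rate_per_min > 0 || kc$evoked_prob > 0) {
    kc_onsets <- with_seed(seeds[[spec$n_epochs + 5L]], {
      out <- numeric(0)
      for (i in which(hyp$stages == "N2")) {
        n_kc <- stats::rpois(1, kc$rate_per_min * spec$epoch_s / 60)
        if (n_kc > 0) {
          out <- c(out, (i - 1) * spec$epoch_s +
                     stats::runif(n_kc, 1, spec$epoch_s - kc$duration_s - 1))
        }
      }
      out
    })
    kc_evoked <- rep(FALSE, length(kc_onsets))
    if (length(onsets) && kc$evoked_prob > 0) {
      ev <- with_seed(seeds[[spec$n_epochs + 6L]], {
        n2_stim <- onsets[stage_at(onsets) == "N2"]
        n2_stim[stats::runif(length(n2_stim)) <= kc$evoked_prob] + 0.5
      })
      ev <- ev[ev + kc$duration_s < duration_s]
      kc_onsets <- c(kc_onsets, ev)
      kc_evoked <- c(kc_evoked, rep(TRUE, length(ev)))
    }
    ord <- order(kc_onsets)
    kc_onsets <- kc_onsets[ord]
    kc_evoked <- kc_evoked[ord]
    wav <- kc_waveform(fs, kc$duration_s, kc$p2p_uv)
    for (t0 in kc_onsets) {
      i0 <- round(t0 * fs) + 1L
      i1 <- i0 + length(wav) - 1L
      if (i1 <= n_total) sig[i0:i1] <- sig[i0:i1] + wav
    }
  }

  kcs <- event_table(kc_onsets, rep("KC", length(kc_onsets)))
  kcs$evoked <- kc_evoked
  list(signal = eeg_signal(sig, fs, channel_labels = "sim"),
       hypnogram = hyp, events = events, kcs = kcs)
}
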