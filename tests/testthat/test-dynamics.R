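# Time-resolved dynamics: transitions, cluster permutation inference,
# event-locked responses, ERPs, and K-complex detection.

test_that("transitions are extracted with full-window coverage and
           matched baselines", {
  hyp <- hypnogram(c("N1", "N1", "N2", "N2", "N2"))
  tr <- extract_transitions(hyp, seed = 1)
  expect_equal(nrow(tr$transitions), 1)
  expect_equal(tr$transitions$time_s, 60)
  expect_equal(tr$transitions$kind, "N1->N2")

  # all-N2: no transitions
  tr2 <- extract_transitions(hypnogram(rep("N2", 20)), seed = 1)
  expect_equal(nrow(tr2$transitions), 0)

  # Markov hypnogram: counts agree with a direct scan oracle
  hyp3 <- simulate_hypnogram(400, seed = 2)
  tr3 <- extract_transitions(hyp3, kinds = "N2->N3", seed = 3)
  st <- hyp3$stages
  scan <- sum(vapply(seq_len(length(st) - 1), function(i) {
    st[i] == "N2" && st[i + 1] == "N3" && i >= 2 && i <= length(st) - 2
  }, logical(1)))
  expect_equal(nrow(tr3$transitions), scan)
  # NREM->REM matches either N2 or N3 into REM
  tr4 <- extract_transitions(hyp3, kinds = "NREM->REM", seed = 3)
  expect_true(all(tr4$transitions$from %in% c("N2", "N3")))
  expect_true(all(tr4$transitions$to == "REM"))
  # baselines keep the pre-transition stage and avoid transition windows
  if (nrow(tr3$baselines)) {
    expect_true(all(tr3$baselines$stage == "N2"))
    for (bt in tr3$baselines$time_s) {
      expect_true(all(abs(tr3$transitions$time_s - bt) >= 120))
    }
  }
})

test_that("transition-locked traces use a 61-sample grid and vanish for
           degenerate baselines", {
  times <- seq(0, 600, by = 2)
  set.seed(4)
  tc <- feature_timecourse(times, list(exponent = rnorm(length(times))))
  tset <- structure(list(
    transitions = tibble::tibble(time_s = c(200, 400), from = "N1",
                                 to = "N2", kind = "N1->N2"),
    baselines = tibble::tibble(time_s = c(200, 400), stage = "N1",
                               kind = "N1->N2"),
    baseline_missing = c(FALSE, FALSE), window_s = 60),
    class = "transition_set")
  tl <- transition_locked_traces(tc, tset)
  expect_length(tl$rel_times, 61)
  expect_equal(dim(tl$transition), c(2, 61))
  # baseline spans identical to transitions: zero difference
  expect_equal(tl$transition, tl$baseline)
})

test_that("cluster permutation test finds planted effects and nothing in
           identical traces", {
  set.seed(5)
  a <- matrix(rnorm(12 * 40), 12)
  r0 <- cluster_permutation_test(a, a, n_perm = 200, seed = 6)
  expect_equal(nrow(r0$clusters), 0)

  tm <- seq(-2, 4, by = 0.1)
  b <- matrix(rnorm(16 * length(tm)), 16)
  c2 <- matrix(rnorm(16 * length(tm)), 16)
  b[, tm >= 0 & tm <= 1] <- b[, tm >= 0 & tm <= 1] + 5
  r1 <- cluster_permutation_test(b, c2, n_perm = 1000, times = tm,
                                 seed = 7)
  sig <- r1$clusters[r1$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_lt(sig$p, 0.025)
  expect_gte(sig$p, 1 / 1000)
  # cluster covers the planted window (within the smoothing of noise)
  expect_lt(abs(sig$t_start - 0), 0.3)
  expect_lt(abs(sig$t_end - 1), 0.3)
  expect_gt(sig$sum_t, 0)

  expect_error(cluster_permutation_test(b, c2, n_perm = 50), "100")
  expect_error(cluster_permutation_test(b[1:4, ], c2[1:4, ],
                                        n_perm = 200), "8 trials")
})

test_that("event-locked exponent traces are flat without events and QC
           R2 is high", {
  spec <- quiet_recording_spec(12, seed = 8)
  spec$transition_matrix <- diag(5)
  spec$initial_stage <- "N2"
  rec <- simulate_sleep_recording(spec)
  onsets <- seq(20, 340, by = 12)
  ep <- epoch_and_reject(rec$signal, onsets, window_s = 10)
  tfr <- multitaper_tfr(ep, decim = 10)
  ev <- event_locked_exponent(
    tfr, fit_settings(aperiodic_mode = "fixed", max_n_peaks = 2),
    fit_step_s = 0.25, average_trials = TRUE)
  expect_lt(max(abs(ev$mean_exponent), na.rm = TRUE), 0.12)
  expect_true(all(ev$r_squared > 0.9, na.rm = TRUE))
})

test_that("event-locked response amplitude scales with the planted
           shift", {
  peaks <- vapply(c(0.2, 0.6), function(mag) {
    spec <- sim_recording_spec(
      fs = 200, n_epochs = 8, initial_stage = "N2",
      transition_matrix = diag(5), seed = 9,
      event_response = list(shift = mag, latency_s = 0.1,
                            duration_s = 0.8, prob = 1),
      kc_params = list(p2p_uv = 0, duration_s = 0.9, rate_per_min = 0,
                       evoked_prob = 0))
    rec <- simulate_sleep_recording(spec)
    ep <- epoch_and_reject(rec$signal, rec$events$onset_s, window_s = 10)
    tfr <- multitaper_tfr(ep, decim = 10)
    ev <- event_locked_exponent(
      tfr, fit_settings(aperiodic_mode = "knee", max_n_peaks = 2),
      fit_step_s = 0.25, average_trials = TRUE)
    io <- ev$times >= 0 & ev$times <= 1.2
    max(ev$mean_exponent[io], na.rm = TRUE)
  }, numeric(1))
  expect_gt(peaks[2], peaks[1])
  expect_gt(peaks[2], 0.3)
})

test_that("ERPs baseline-correct relatively and average out noise", {
  fs <- 200
  n_time <- 10 * fs
  t_rel <- (seq_len(n_time) - (5 * fs + 1)) / fs
  wave <- ifelse(t_rel >= 0 & t_rel <= 1,
                 -30 * sin(2 * pi * pmax(t_rel, 0)), 0)
  mk_epochs <- function(n, noise, add_wave = TRUE, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    eps <- t(vapply(seq_len(n),
                    function(i) 100 + add_wave * wave +
                      rnorm(n_time, 0, noise),
                    numeric(n_time)))
    structure(list(epochs = eps, t_zero = 5 * fs + 1, fs = fs,
                   kept_mask = rep(TRUE, n), onsets = seq_len(n),
                   n_dropped_edge = 0L), class = "epoch_set")
  }
  # constant epochs -> zero waveform
  e0 <- erp(mk_epochs(5, 0))
  base0 <- ifelse(t_rel >= 0 & t_rel <= 1, wave / 100, 0)
  expect_equal(e0$erp, base0, tolerance = 1e-10)

  # residual noise shrinks with the trial count
  set.seed(10)
  r5 <- erp(mk_epochs(5, 5))
  r45 <- erp(mk_epochs(45, 5))
  rmse <- function(r) sqrt(mean((r$erp - base0)^2))
  expect_lt(rmse(r45), rmse(r5))
  # with identical noise, pre-onset output is unaffected by whether the
  # epochs carry post-onset content
  w1 <- erp(mk_epochs(10, 5, add_wave = TRUE, seed = 99))
  w0 <- erp(mk_epochs(10, 5, add_wave = FALSE, seed = 99))
  pre <- t_rel < 0
  expect_equal(w1$erp[pre], w0$erp[pre], tolerance = 1e-12)
  expect_gt(max(abs(w1$erp[!pre] - w0$erp[!pre])), 0.1)
})

test_that("K-complex detection applies amplitude, duration and score
           criteria", {
  fs <- 200
  mk <- function(p2p, dur) {
    x <- rnorm(fs * 30, 0, 3)
    w <- kc_waveform(fs, dur, p2p)
    i0 <- 10 * fs
    x[i0:(i0 + length(w) - 1)] <- x[i0:(i0 + length(w) - 1)] + w
    x
  }
  set.seed(11)
  hits <- kc_detect(mk(75, 0.9), fs = fs)
  expect_equal(nrow(hits), 1)
  expect_lt(abs(hits$onset_s - 10), 0.3)
  expect_gt(hits$p2p_uv, 50)
  expect_true(hits$duration_s >= 0.48 & hits$duration_s <= 1.5)
  expect_gte(hits$score, 0.8)

  expect_equal(nrow(kc_detect(mk(30, 0.9), fs = fs)), 0)   # too small
  expect_equal(nrow(kc_detect(mk(75, 2.0), fs = fs)), 0)   # too long
  expect_error(kc_detect(mk(75, 0.9), fs = 80), "100")

  # evoked flag: onset within 2 s after a stimulus
  ev <- kc_detect(mk(75, 0.9), fs = fs, stim_onsets = c(8.5, 20))
  expect_true(ev$evoked[1])
  ev2 <- kc_detect(mk(75, 0.9), fs = fs, stim_onsets = 20)
  expect_false(ev2$evoked[1])
})

test_that("the generator's injected K-complexes are recovered by the
           detector", {
  spec <- quiet_recording_spec(6, seed = 12)
  spec$transition_matrix <- diag(5)
  spec$initial_stage <- "N2"
  spec$kc_params <- list(p2p_uv = 150, duration_s = 0.9,
                         rate_per_min = 2, evoked_prob = 0)
  rec <- simulate_sleep_recording(spec)
  det <- kc_detect(rec$signal)
  expect_gt(nrow(det), 0)
  # most detections align with an injected event (within 0.5 s)
  frac_matched <- mean(vapply(det$onset_s, function(t0) {
    any(abs(rec$kcs$onset_s - t0) < 0.5)
  }, logical(1)))
  expect_gt(frac_matched, 0.7)
})

test_that("whole-night report annotates every epoch with its stage", {
  one <- simulate_sleep_recording(quiet_recording_spec(1, seed = 13))
  r1 <- whole_night_report(one$signal, one$hypnogram,
                           fit_settings(aperiodic_mode = "fixed",
                                        max_n_peaks = 2))
  expect_equal(nrow(r1), 1)

  qn <- quiet_night()
  expect_equal(nrow(qn$report), 150)
  expect_identical(qn$report$stage, qn$rec$hypnogram$stages)
  # stage-mean exponents preserve the generator's depth ordering
  m <- tapply(qn$report$exponent, qn$report$stage, mean, na.rm = TRUE)
  expect_true(m[["Wake"]] < m[["N1"]])
  expect_true(m[["N1"]] < m[["N2"]])
  expect_true(m[["N2"]] < m[["N3"]])
  expect_true(m[["REM"]] < m[["N2"]])
})
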