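# Spectral parameterization core: aperiodic model, knee frequency, full
# fits, range grids, pre-knee exponent, BIC, exclusion rules, and
# time-resolved fitting.

test_that("aperiodic model and knee frequency satisfy their identities", {
  expect_equal(aperiodic_model(10, offset = 0, knee = 0, exponent = 1), -1)
  expect_equal(aperiodic_model(1, offset = 0, knee = 0, exponent = 2.3), 0)
  k <- 13.13^1.25
  expect_equal(aperiodic_model(13.13, offset = 1.5, knee = k,
                               exponent = 1.25),
               1.5 - log10(2 * k), tolerance = 1e-12)
  expect_error(aperiodic_model(-1, 0, 0, 1), "positive")

  expect_equal(knee_frequency(list(mode = "knee", knee = 1, exponent = 1)),
               1)
  expect_equal(knee_frequency(list(mode = "knee", knee = 100,
                                   exponent = 2)), 10)
  expect_equal(knee_frequency(list(mode = "knee", knee = k,
                                   exponent = 1.25)), 13.13,
               tolerance = 1e-10)
  expect_true(is.na(knee_frequency(list(mode = "fixed", knee = 0,
                                        exponent = 1))))
  expect_error(knee_frequency(list(mode = "knee", knee = -1,
                                   exponent = 1)), "knee")
})

test_that("noiseless exact-model-class spectra are recovered exactly", {
  ps <- simulate_power_spectrum(fig_spectrum_spec(noise_sd = 0))
  fit <- fit_spectral_model(ps, fit_settings(aperiodic_mode = "knee"))
  expect_equal(fit$aperiodic$offset, 1.5, tolerance = 1e-2)
  expect_equal(fit_exponent(fit), 1.25, tolerance = 1e-2)
  expect_equal(fit_knee_frequency(fit), 13.13, tolerance = 0.1)
  expect_equal(nrow(fit$peaks), 2)
  expect_equal(sort(fit$peaks$center), c(10, 30), tolerance = 1e-2)
  expect_gt(fit$r_squared, 0.999)

  # peak-free power law in fixed mode
  ps2 <- simulate_power_spectrum(sim_spectrum_spec(
    mode = "fixed", offset = 1, exponent = 1.5, noise_sd = 0))
  fit2 <- fit_spectral_model(ps2, fit_settings(aperiodic_mode = "fixed"))
  expect_equal(fit_exponent(fit2), 1.5, tolerance = 1e-3)
  expect_equal(nrow(fit2$peaks), 0)
})

test_that("fits validate their inputs", {
  ps <- simulate_power_spectrum(fig_spectrum_spec())
  expect_error(fit_spectral_model(ps, fit_settings(fit_range = c(50, 60))),
               "10 points")
  bad <- list(freqs = ps$freqs, powers = ps$powers)
  bad$powers[100] <- 0
  expect_error(fit_spectral_model(bad, fit_settings()), "positive")
  expect_error(fit_settings(fit_range = c(45, 1)), "f_lo")
})

test_that("exponent recovery holds across random synthetic spectra", {
  # ground-truth round-trip oracle over the generator's model class
  set.seed(99)
  errs <- vapply(1:50, function(i) {
    mode <- sample(c("fixed", "knee"), 1)
    x <- runif(1, 0.8, 2.5)
    npk <- sample(0:2, 1)
    pks <- if (npk > 0) {
      lapply(seq_len(npk),
             function(j) c(runif(1, 4, 40), runif(1, 0.3, 1),
                           runif(1, 1.5, 6)))
    }
    sp <- sim_spectrum_spec(
      mode = mode, offset = runif(1, 0, 2),
      knee_freq = if (mode == "knee") runif(1, 3, 20),
      exponent = x, peaks = pks, noise_sd = 0.05, seed = i)
    fit <- fit_spectral_model(simulate_power_spectrum(sp),
                              fit_settings(aperiodic_mode = mode))
    abs(fit_exponent(fit) - x)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("knee frequency is recovered within 5% at low noise", {
  kfs <- vapply(1:10, function(s) {
    ps <- simulate_power_spectrum(fig_spectrum_spec(seed = s))
    fit_knee_frequency(fit_spectral_model(
      ps, fit_settings(aperiodic_mode = "knee")))
  }, numeric(1))
  expect_lt(abs(median(kfs) - 13.13) / 13.13, 0.05)
})

test_that("adding the knee never worsens the fit on knee-free data", {
  # nested models: on pure power laws the knee fit's error is bounded by
  # the fixed fit's up to numerical tolerance
  for (s in 1:5) {
    ps <- simulate_power_spectrum(sim_spectrum_spec(
      mode = "fixed", offset = 1, exponent = 1.3, noise_sd = 0.05,
      seed = s))
    fk <- fit_spectral_model(ps, fit_settings(aperiodic_mode = "knee",
                                              max_n_peaks = 0))
    ff <- fit_spectral_model(ps, fit_settings(aperiodic_mode = "fixed",
                                              max_n_peaks = 0))
    expect_lte(fk$error_mae, ff$error_mae + 1e-4)
  }
})

test_that("knee frequency couples negatively with the fixed-model
           exponent", {
  kfs <- seq(3, 25, length.out = 25)
  exps <- vapply(seq_along(kfs), function(i) {
    ps <- simulate_power_spectrum(sim_spectrum_spec(
      mode = "knee", offset = 1.5, knee_freq = kfs[i], exponent = 1.25,
      noise_sd = 0.02, seed = i))
    fit_exponent(fit_spectral_model(
      ps, fit_settings(aperiodic_mode = "fixed", max_n_peaks = 0)))
  }, numeric(1))
  expect_lt(cor(kfs, exps, method = "spearman"), -0.5)
})

test_that("fit_grid covers ranges x windows and degenerates to a single
           fit", {
  x <- simulate_aperiodic_timeseries(1.5, NULL, 120, 200, seed = 3)
  g1 <- fit_grid(x, fs = 200, ranges = list(c(1, 45)),
                 welch_windows = 15,
                 settings = fit_settings(max_n_peaks = 0))
  expect_equal(nrow(g1), 1)
  direct <- fit_spectral_model(welch_psd(x, fs = 200),
                               fit_settings(max_n_peaks = 0))
  expect_equal(g1$exponent, fit_exponent(direct))
  expect_equal(g1$r_squared, direct$r_squared)

  # scale-free input: one true exponent across ranges and windows
  g <- fit_grid(x, fs = 200,
                ranges = list(c(1, 30), c(1, 45), c(10, 30), c(20, 40)),
                welch_windows = c(10, 15),
                settings = fit_settings(max_n_peaks = 0))
  expect_true(all(g$ok))
  expect_lt(max(g$exponent) - min(g$exponent), 0.25)
  # on the exact (noise-free) model the property is sharp
  direct_exps <- vapply(list(c(1, 30), c(1, 45), c(10, 30), c(20, 40)),
                        function(r) {
    ps <- simulate_power_spectrum(sim_spectrum_spec(
      f_range = c(1, 45), mode = "fixed", offset = 1, exponent = 1.5,
      noise_sd = 0))
    fit_exponent(fit_spectral_model(ps, fit_settings(
      aperiodic_mode = "fixed", fit_range = r)))
  }, numeric(1))
  expect_lt(max(direct_exps) - min(direct_exps), 0.02)
})

test_that("pre-knee exponent quantifies the sub-knee slope", {
  # Lorentzian plateau: below the knee the spectrum is nearly flat
  ps <- simulate_power_spectrum(sim_spectrum_spec(
    mode = "knee", offset = 1.5, knee_freq = 20, exponent = 2,
    noise_sd = 0))
  kfit <- fit_spectral_model(ps, fit_settings(aperiodic_mode = "knee"))
  pre <- pre_knee_exponent(ps, kfit)
  expect_lt(fit_exponent(pre), 0.35)

  # two-regime spectrum: slope 0.5 below a sharp 12-Hz bend, 2.5 above
  freqs <- seq(1, 45, by = 0.25)
  lp <- 1 - 0.5 * log10(freqs) - 2 * log10(1 + (freqs / 12)^8) / 8
  ps2 <- power_spectrum(freqs, 10^lp)
  kfit2 <- fit_spectral_model(ps2, fit_settings(aperiodic_mode = "knee"))
  expect_gt(fit_knee_frequency(kfit2), 2)
  pre2 <- pre_knee_exponent(ps2, kfit2)
  expect_lt(abs(fit_exponent(pre2) - 0.5), 0.1)

  # knee below 2 Hz is rejected
  fake <- kfit
  fake$aperiodic$knee <- 1.5^fake$aperiodic$exponent
  expect_error(pre_knee_exponent(ps, fake), "2 Hz")
})

test_that("BIC and model comparison follow the stated formula", {
  mk_fit <- function(mode, n_peaks, mae, n = 100) {
    structure(list(
      aperiodic = structure(list(mode = mode, offset = 1,
                                 knee = if (mode == "knee") 4,
                                 exponent = 1), class = "aperiodic_fit"),
      peaks = tibble::tibble(center = numeric(n_peaks),
                             height = numeric(n_peaks),
                             bandwidth = numeric(n_peaks)),
      r_squared = 0.99, error_mae = mae, n_points = n,
      settings = fit_settings(), converged = TRUE),
      class = "spectral_fit")
  }
  # direct arithmetic oracle: N = 100, error 0.1, fixed, 0 peaks
  expect_equal(bic(mk_fit("fixed", 0, 0.1)),
               100 * log(0.01) + 2 * log(100), tolerance = 1e-12)
  # np counts peaks at 3 parameters each
  expect_equal(bic(mk_fit("fixed", 2, 0.1)),
               100 * log(0.01) + 8 * log(100), tolerance = 1e-12)
  # equal error and peak count: knee has one extra parameter
  cmp <- compare_models(mk_fit("knee", 1, 0.1), mk_fit("fixed", 1, 0.1))
  expect_equal(cmp$delta_bic, log(100), tolerance = 1e-12)
  expect_equal(cmp$preferred, "fixed")
  # delta of -7 is strong evidence for the knee model
  cmp2 <- compare_models(mk_fit("knee", 0, 0.1 * exp(-7 / 200)),
                         mk_fit("fixed", 1, 0.1))
  expect_equal(cmp2$preferred, "knee")
  expect_lt(cmp2$delta_bic, -6)
  expect_equal(cmp2$evidence, "strong")
  expect_error(bic(mk_fit("fixed", 0, 0)), "zero")
  expect_error(compare_models(mk_fit("knee", 0, 0.1, n = 50),
                              mk_fit("fixed", 0, 0.1, n = 100)), "N")
})

test_that("exclusion filters apply the 2-SD rules per group", {
  expect_warning(keep <- exclusion_filters(c(10, 10, 10, 10)),
                 "degenerate")
  expect_true(all(keep))
  # mean 15, sample SD 10: 30 is within 2 SD
  expect_true(all(exclusion_filters(c(10, 10, 10, 30))))
  # one value 3 SD below the mean under the one-sided lower rule
  set.seed(20)
  r2 <- c(rnorm(20, 0.95, 0.01), NA)
  r2[21] <- mean(r2[1:20]) - 3 * sd(r2[1:20])
  keep2 <- exclusion_filters(r2, rule = "lower")
  expect_false(keep2[21])
  expect_gte(sum(keep2[1:20]), 18)
  # grouping applies the rule within groups: a within-group outlier is
  # caught only when the group structure is used
  g <- rep(c("a", "b"), each = 10)
  vals <- c(rep(c(4.9, 5.0, 5.1), 3), 7, rep(c(49.9, 50, 50.1), 3), 50)
  expect_true(all(exclusion_filters(vals)))          # pooled SD hides it
  expect_false(exclusion_filters(vals, group = g)[10])
  expect_true(all(exclusion_filters(vals, group = g)[-10]))
})

test_that("time-resolved fitting is stable, tracks steps, and leaves
           gaps", {
  fs <- 200
  x1 <- simulate_aperiodic_timeseries(1, NULL, 120, fs, seed = 10)
  x2 <- simulate_aperiodic_timeseries(2, NULL, 120, fs, seed = 11)
  sg <- sliding_psd(c(x1, x2), fs = fs, welch_window_s = 5)
  tc <- time_resolved_fit(sg, fit_settings(aperiodic_mode = "fixed",
                                           max_n_peaks = 0))
  e <- tc$values$exponent
  stable <- e[sg$times < 100]
  expect_lt(sd(stable), 0.1)
  expect_lt(abs(mean(stable) - 1), 0.1)
  # the trace transitions within one window length (20 s) of t0 = 120
  expect_lt(mean(e[sg$times < 110]), 1.2)
  expect_gt(mean(e[sg$times > 130]), 1.8)
  expect_false(attr(tc, "flagged"))

  # an all-zero stretch produces gaps, not an abort
  x3 <- c(x1[1:(40 * fs)], rep(0, 30 * fs), x1[1:(40 * fs)])
  sg3 <- sliding_psd(x3, fs = fs, welch_window_s = 5)
  tc3 <- time_resolved_fit(sg3, fit_settings(aperiodic_mode = "fixed"))
  mid <- sg3$times > 55 & sg3$times < 60
  expect_true(all(is.na(tc3$values$exponent[mid])))
  expect_true(any(is.finite(tc3$values$exponent)))
})
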