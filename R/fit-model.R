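# Full spectral parameterization: robust aperiodic fit, iterative Gaussian
# peak extraction from the flattened spectrum, joint peak refinement, and
# a final aperiodic fit on the peak-subtracted spectrum.

#' Spectral model fit settings
#'
#' @param fit_range Frequency range `c(f_lo, f_hi)` in Hz (default 1-45).
#' @param aperiodic_mode `"fixed"` (single exponent) or `"knee"`.
#' @param peak_width_limits Allowed peak bandwidths in Hz (default 1-12;
#'   bandwidth = 2 * Gaussian sd).
#' @param max_n_peaks Maximum number of peaks (default 8).
#' @param min_peak_height Absolute height threshold in log10 power
#'   (default 0).
#' @param peak_threshold Relative threshold in multiples of the flattened
#'   spectrum's SD (default 2).
#' @param exponent_max Upper optimizer bound for the exponent (default 8).
#' @param n_iter Maximum alternations of the peak-fit / aperiodic-refit
#'   stages (default 5; iteration stops early once the exponent
#'   stabilizes).
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(fit_range = c(1, 45),
                         aperiodic_mode = c("fixed", "knee"),
                         peak_width_limits = c(1, 12), max_n_peaks = 8,
                         min_peak_height = 0, peak_threshold = 2,
                         exponent_max = 8, n_iter = 5) {
  aperiodic_mode <- match.arg(aperiodic_mode)
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2]) {
    stopf("`fit_range` must be c(f_lo, f_hi) with f_lo < f_hi")
  }
  if (peak_width_limits[1] >= peak_width_limits[2]) {
    stopf("`peak_width_limits` must be increasing")
  }
  structure(list(fit_range = as.numeric(fit_range),
                 aperiodic_mode = aperiodic_mode,
                 peak_width_limits = as.numeric(peak_width_limits),
                 max_n_peaks = as.integer(max_n_peaks),
                 min_peak_height = min_peak_height,
                 peak_threshold = peak_threshold,
                 exponent_max = exponent_max,
                 n_iter = as.integer(n_iter)),
            class = "fit_settings")
}

gaussian_sum <- function(freqs, peaks) {
  # peaks: matrix with columns center, height, sd
  if (is.null(peaks) || nrow(peaks) == 0L) return(numeric(length(freqs)))
  g <- exp(-(outer(freqs, peaks[, 1], "-"))^2 /
             rep(2 * peaks[, 3]^2, each = length(freqs)))
  as.numeric(g %*% peaks[, 2])
}

# Iterative peak search on the flattened spectrum. Returns a guess matrix
# (center, height, sd).
guess_peaks <- function(freqs, flat, settings) {
  sd_lims <- settings$peak_width_limits / 2
  guesses <- NULL
  work <- flat
  for (i in seq_len(settings$max_n_peaks)) {
    idx <- which.max(work)
    height <- work[idx]
    sd_flat <- stats::sd(work)
    if (!is.finite(sd_flat) || sd_flat == 0) break
    # 1e-6 log10-power floor guards against numerically flat spectra
    if (height <= max(settings$peak_threshold * sd_flat,
                      settings$min_peak_height, 1e-6)) {
      break
    }
    center <- freqs[idx]
    # half-height width from the nearer crossing
    half <- height / 2
    ri <- idx
    while (ri < length(work) && work[ri] > half) ri <- ri + 1L
    li <- idx
    while (li > 1L && work[li] > half) li <- li - 1L
    d_r <- if (work[ri] <= half) freqs[ri] - center else NA_real_
    d_l <- if (work[li] <= half) center - freqs[li] else NA_real_
    hwhm <- suppressWarnings(min(d_r, d_l, na.rm = TRUE))
    if (!is.finite(hwhm)) hwhm <- mean(sd_lims) * 1.177  # fallback
    sd_g <- min(max(2 * hwhm / 2.355, sd_lims[1]), sd_lims[2])
    # subtract before the edge test so the search always progresses
    work <- work - height * exp(-(freqs - center)^2 / (2 * sd_g^2))
    edge_ok <- (center - min(freqs)) > sd_g && (max(freqs) - center) > sd_g
    if (edge_ok) guesses <- rbind(guesses, c(center, height, sd_g))
  }
  if (is.null(guesses)) return(NULL)
  # drop overlapping guesses (keep the taller of any pair closer than
  # 0.75 x the sum of their sds)
  ord <- order(guesses[, 1])
  guesses <- guesses[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(guesses))
  if (nrow(guesses) > 1L) {
    for (i in seq_len(nrow(guesses) - 1L)) {
      j <- i + 1L
      if (guesses[j, 1] - guesses[i, 1] <
          0.75 * (guesses[i, 3] + guesses[j, 3])) {
        drop <- if (guesses[i, 2] >= guesses[j, 2]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  guesses[keep, , drop = FALSE]
}

# Joint bounded refinement of all Gaussians against the flattened
# spectrum.
refine_peaks <- function(freqs, flat, guesses, settings) {
  if (is.null(guesses) || nrow(guesses) == 0L) return(guesses)
  sd_lims <- settings$peak_width_limits / 2
  np <- nrow(guesses)
  p0 <- as.numeric(t(guesses))
  lower <- upper <- numeric(3 * np)
  for (i in seq_len(np)) {
    o <- 3 * (i - 1)
    lower[o + 1] <- max(min(freqs), guesses[i, 1] - 1.5 * guesses[i, 3])
    upper[o + 1] <- min(max(freqs), guesses[i, 1] + 1.5 * guesses[i, 3])
    lower[o + 2] <- 0
    upper[o + 2] <- Inf
    lower[o + 3] <- sd_lims[1]
    upper[o + 3] <- sd_lims[2]
  }
  obj <- function(p) {
    m <- matrix(p, ncol = 3, byrow = TRUE)
    sum((flat - gaussian_sum(freqs, m))^2)
  }
  grad <- function(p) {
    m <- matrix(p, ncol = 3, byrow = TRUE)
    dfc <- outer(freqs, m[, 1], "-")            # n x np
    g <- exp(-dfc^2 / rep(2 * m[, 3]^2, each = length(freqs)))
    r <- flat - as.numeric(g %*% m[, 2])
    gc <- -2 * colSums(r * g * dfc) * m[, 2] / m[, 3]^2
    gh <- -2 * colSums(r * g)
    gs <- -2 * colSums(r * g * dfc^2) * m[, 2] / m[, 3]^3
    as.numeric(t(cbind(gc, gh, gs)))
  }
  res <- tryCatch(
    stats::optim(p0, obj, gr = grad, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 150)),
    error = function(e) NULL)
  if (is.null(res)) return(guesses)
  matrix(res$par, ncol = 3, byrow = TRUE)
}

#' Fit a spectral parameterization model to a power spectrum
#'
#' Decomposes a power spectrum (in log10 power) into an aperiodic
#' component -- `offset - log10(knee + f^exponent)`, with the knee fixed
#' at 0 in `"fixed"` mode -- plus Gaussian oscillatory peaks. The
#' algorithm: (1) robust aperiodic fit (least squares, then refit on the
#' points hugging the aperiodic component); (2) iterative peak search on
#' the flattened spectrum, accepting maxima above
#' `peak_threshold * SD(flattened)` and `min_peak_height`; (3) joint
#' bounded refinement of all Gaussians; (4) final aperiodic fit on the
#' peak-subtracted spectrum.
#'
#' @param spectrum A [power_spectrum()] (single channel) or a list with
#'   `freqs` and `powers`.
#' @param settings A [fit_settings()].
#' @return An object of class `spectral_fit` with elements `aperiodic`
#'   (class `aperiodic_fit`: `mode`, `offset`, `knee`, `exponent`),
#'   `peaks` (tibble: center, height, bandwidth), `r_squared` (squared
#'   Pearson correlation of model and data log powers), `error_mae` (mean
#'   absolute log10-power error), `n_points`, `settings`, and `converged`.
#' @examples
#' ps <- simulate_power_spectrum(sim_spectrum_spec(
#'   mode = "knee", offset = 1.5, knee_freq = 13.13, exponent = 1.25,
#'   peaks = list(c(10, 0.9, 2.5), c(30, 0.6, 5)), seed = 1))
#' fit <- fit_spectral_model(ps, fit_settings(aperiodic_mode = "knee"))
#' @export
fit_spectral_model <- function(spectrum, settings = fit_settings()) {
  stopifnot(inherits(settings, "fit_settings"))
  freqs <- spectrum$freqs
  powers <- spectrum$powers
  if (is.matrix(powers)) powers <- powers[, 1L]
  sel <- freqs >= settings$fit_range[1] & freqs <= settings$fit_range[2]
  freqs <- freqs[sel]
  powers <- powers[sel]
  if (length(freqs) < 10L) {
    stopf("spectrum must cover the fit range with >= 10 points")
  }
  if (any(powers <= 0) || any(!is.finite(powers))) {
    stopf("powers must be positive and finite within the fit range")
  }
  y <- log10(powers)
  mode <- settings$aperiodic_mode
  ap0 <- robust_ap_fit(freqs, y, mode, settings$exponent_max)
  # Iterate the flatten / peak-fit / aperiodic-refit stages: because the
  # initial aperiodic fit is biased by oscillatory peaks (and vice
  # versa), alternating the two sub-fits until the exponent stabilizes
  # converges to the joint solution on exact-model-class spectra.
  ap <- ap0
  peaks <- NULL
  for (iter in seq_len(settings$n_iter)) {
    flat <- y - aperiodic_model(freqs, ap$offset, ap$knee, ap$exponent)
    guesses <- guess_peaks(freqs, flat, settings)
    peaks <- refine_peaks(freqs, flat, guesses, settings)
    peak_component <- gaussian_sum(freqs, peaks)
    ap_new <- simple_ap_fit(freqs, y - peak_component, mode, init = ap,
                            exponent_max = settings$exponent_max)
    done <- abs(ap_new$exponent - ap$exponent) < 1e-3
    ap <- ap_new
    if (done) break
  }
  model <- aperiodic_model(freqs, ap$offset, ap$knee, ap$exponent) +
    peak_component
  r2 <- if (stats::sd(model) > 0) stats::cor(y, model)^2 else NA_real_
  mae <- mean(abs(y - model))
  peaks_tbl <- if (is.null(peaks) || nrow(peaks) == 0L) {
    tibble::tibble(center = numeric(0), height = numeric(0),
                   bandwidth = numeric(0))
  } else {
    tibble::tibble(center = peaks[, 1], height = peaks[, 2],
                   bandwidth = 2 * peaks[, 3])
  }
  aperiodic <- structure(list(mode = mode, offset = ap$offset,
                              knee = if (mode == "knee") ap$knee else NULL,
                              exponent = ap$exponent),
                         class = "aperiodic_fit")
  structure(list(aperiodic = aperiodic, peaks = peaks_tbl,
                 r_squared = r2, error_mae = mae,
                 n_points = length(freqs), settings = settings,
                 converged = ap$converged),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  ap <- x$aperiodic
  kf <- if (ap$mode == "knee") sprintf(", knee_freq=%.2f Hz",
                                       knee_frequency(ap)) else ""
  cat(sprintf(
    "<spectral_fit> %s mode: offset=%.3f, exponent=%.3f%s | %d peak(s), R2=%.4f, MAE=%.4f\n",
    ap$mode, ap$offset, ap$exponent, kf, nrow(x$peaks), x$r_squared,
    x$error_mae))
  invisible(x)
}

#' Exponent of a spectral fit
#' @param fit A `spectral_fit`.
#' @return The aperiodic exponent.
#' @export
fit_exponent <- function(fit) fit$aperiodic$exponent

#' Knee frequency of a spectral fit
#' @param fit A `spectral_fit`.
#' @return Knee frequency in Hz (`NA` for fixed mode).
#' @export
fit_knee_frequency <- function(fit) knee_frequency(fit$aperiodic)
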