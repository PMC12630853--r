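# Aperiodic model evaluation and robust aperiodic fitting.
#
# The aperiodic component is the Lorentzian-style form
#   log10 L(f) = b - log10(k + f^x)
# with offset b (log10 power), knee constant k >= 0 and exponent x; fixed
# mode is the k = 0 special case (a straight line of slope -x in log-log
# coordinates). The knee frequency -- the bend in the spectrum,
# interpreted as a population timescale -- is k^(1/x).

#' Evaluate the aperiodic model in log10 power
#'
#' @param freqs Frequencies in Hz (> 0).
#' @param offset Offset b in log10-power units.
#' @param knee Knee constant k (>= 0; 0 for fixed mode).
#' @param exponent Exponent x.
#' @return log10 power at `freqs`.
#' @export
aperiodic_model <- function(freqs, offset, knee = 0, exponent) {
  if (any(freqs <= 0)) stopf("`freqs` must be positive")
  if (knee < 0) stopf("`knee` must be non-negative")
  offset - log10(knee + freqs^exponent)
}

#' Knee frequency of an aperiodic fit
#'
#' Converts the knee constant to the interpretable knee frequency via
#' `knee_freq = k^(1/x)`.
#'
#' @param fit An `aperiodic_fit` (see [fit_spectral_model()]) or a list
#'   with elements `mode`, `knee`, `exponent`.
#' @return Knee frequency in Hz, or `NA` for fixed-mode fits.
#' @export
knee_frequency <- function(fit) {
  if (fit$mode != "knee") return(NA_real_)
  if (is.null(fit$knee) || fit$knee < 0) stopf("knee constant must be >= 0")
  fit$knee^(1 / fit$exponent)
}

# Bounded least-squares aperiodic fit in log10 power. The offset enters
# the model linearly, so it is profiled out analytically and the search
# runs over (exponent) or (knee, exponent) only; the knee is optimized on
# a log10(k + 1) scale so that k = 0 (the fixed special case) and large
# knee constants are equally reachable. Ties across starts are broken by
# lowest error.
# Returns list(offset, knee, exponent, mode, sse, converged).
simple_ap_fit <- function(freqs, log_powers, mode, init = NULL,
                          exponent_max = 8) {
  lf <- log10(freqs)
  n <- length(freqs)
  y <- log_powers
  if (mode == "fixed") {
    # closed form: OLS of y on -lf, exponent clamped to [0, exponent_max]
    x_hat <- -stats::cov(y, lf) / stats::var(lf)
    x_hat <- min(max(x_hat, 0), exponent_max)
    b_hat <- mean(y) + x_hat * mean(lf)
    sse <- sum((y - (b_hat - x_hat * lf))^2)
    return(list(offset = b_hat, knee = 0, exponent = x_hat, mode = mode,
                sse = sse, converged = TRUE))
  }
  # knee mode: profile the offset, search over (u, x), u = log10(k + 1)
  sse_ux <- function(p) {
    k <- 10^p[1] - 1
    pred0 <- -log10(k + freqs^p[2])
    b <- mean(y - pred0)
    sum((y - b - pred0)^2)
  }
  lf_n <- log(freqs)
  # the profiled residual has zero mean, so dSSE/dtheta reduces to
  # -2 * sum(r * dpred0/dtheta)
  grad_ux <- function(p) {
    k <- 10^p[1] - 1
    fx <- freqs^p[2]
    tt <- k + fx
    pred0 <- -log10(tt)
    r <- y - mean(y - pred0) - pred0
    c(2 * 10^p[1] * sum(r / tt),
      (2 / log(10)) * sum(r * fx * lf_n / tt))
  }
  k_max <- max(freqs)^exponent_max
  u_max <- log10(k_max + 1)
  fx <- simple_ap_fit(freqs, y, "fixed", exponent_max = exponent_max)
  x0 <- max(fx$exponent, 0.1)
  starts <- list(c(0, x0),
                 c(log10(stats::median(freqs)^x0 + 1), min(2 * x0,
                                                           exponent_max)),
                 c(log10((0.25 * max(freqs))^x0 + 1), x0))
  if (!is.null(init) && !is.null(init$knee)) {
    starts <- c(list(c(log10(init$knee + 1), init$exponent)), starts)
  }
  lower <- c(0, 0)
  upper <- c(u_max, exponent_max)
  best <- NULL
  converged <- FALSE
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0, sse_ux, gr = grad_ux, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      converged <- TRUE
    }
  }
  # Nelder-Mead polish of the best solution off the box boundary
  if (!is.null(best) && all(best$par > lower + 1e-9) &&
      all(best$par < upper - 1e-9)) {
    res2 <- tryCatch(
      stats::optim(best$par, sse_ux,
                   control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res2) && res2$value < best$value &&
        all(res2$par >= lower) && all(res2$par <= upper)) {
      best <- res2
    }
  }
  if (is.null(best)) {
    return(list(offset = fx$offset, knee = 0, exponent = fx$exponent,
                mode = mode, sse = fx$sse, converged = FALSE))
  }
  k <- 10^best$par[1] - 1
  x <- best$par[2]
  pred0 <- -log10(k + freqs^x)
  list(offset = mean(y - pred0), knee = k, exponent = x, mode = mode,
       sse = best$value, converged = converged)
}

# Robust aperiodic fit: initial fit, flatten, keep the points at or below
# the 2.5th percentile of the positive residuals (i.e. points hugging the
# aperiodic component, excluding oscillatory peaks), refit on those.
robust_ap_fit <- function(freqs, log_powers, mode, exponent_max = 8) {
  fit1 <- simple_ap_fit(freqs, log_powers, mode, exponent_max = exponent_max)
  flat <- log_powers - aperiodic_model(freqs, fit1$offset, fit1$knee,
                                       fit1$exponent)
  flat[flat < 0] <- 0
  thresh <- stats::quantile(flat, 0.025, names = FALSE)
  keep <- flat <= thresh
  if (sum(keep) < 4L) return(fit1)
  fit2 <- simple_ap_fit(freqs[keep], log_powers[keep], mode, init = fit1,
                        exponent_max = exponent_max)
  fit2
}
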