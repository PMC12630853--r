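# Model comparison via BIC and outlier exclusion rules.

#' Bayesian Information Criterion of a spectral fit
#'
#' `BIC = N * log(mse) + np * log(N)` (natural log), where
#' `mse = error_mae^2` (the squared model error parameter), `N` is the
#' number of fitted frequencies and `np = 3 * n_peaks + n_ap_params` with
#' 2 aperiodic parameters in fixed mode (offset, exponent) and 3 in knee
#' mode.
#'
#' @param fit A `spectral_fit`.
#' @return The BIC value (lower is better).
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "spectral_fit"))
  mse <- fit$error_mae^2
  if (mse <= 0) stopf("zero model error: BIC undefined")
  n_ap <- if (fit$aperiodic$mode == "knee") 3L else 2L
  np <- nrow(fit$peaks) * 3L + n_ap
  fit$n_points * log(mse) + np * log(fit$n_points)
}

#' Compare knee and fixed model fits via BIC
#'
#' `delta_bic = BIC(knee) - BIC(fixed)`; negative values favor the knee
#' model. Evidence labels follow the conventional bands on the absolute
#' difference: 0-2 weak, 2-6 positive, > 6 strong.
#'
#' @param fit_knee,fit_fixed `spectral_fit`s of both modes on the same
#'   spectrum and range (equal `n_points`).
#' @return A list with `delta_bic`, `preferred` (`"knee"`/`"fixed"`), and
#'   `evidence` (`"weak"`, `"positive"`, `"strong"`).
#' @export
compare_models <- function(fit_knee, fit_fixed) {
  if (fit_knee$aperiodic$mode != "knee" ||
      fit_fixed$aperiodic$mode != "fixed") {
    stopf("`fit_knee` must be knee mode and `fit_fixed` fixed mode")
  }
  if (fit_knee$n_points != fit_fixed$n_points) {
    stopf("fits must cover the same spectrum (mismatched N)")
  }
  d <- bic(fit_knee) - bic(fit_fixed)
  a <- abs(d)
  evidence <- if (a <= 2) "weak" else if (a <= 6) "positive" else "strong"
  list(delta_bic = d,
       preferred = if (d < 0) "knee" else "fixed",
       evidence = evidence)
}

#' Standard-deviation outlier exclusion
#'
#' Two-sided rule (for knee frequencies, per subject x stage group): keep
#' values within 2 SD of the group mean. One-sided lower rule (for R^2):
#' keep values at or above mean - 2 SD. Degenerate groups (SD = 0 or
#' fewer than 3 values) keep everything with a warning.
#'
#' @param values Numeric vector.
#' @param rule `"two_sided"` or `"lower"`.
#' @param group Optional grouping vector (the rule is applied within each
#'   group).
#' @param n_sd Number of standard deviations (default 2).
#' @return Logical keep-mask of `length(values)`.
#' @export
exclusion_filters <- function(values, rule = c("two_sided", "lower"),
                              group = NULL, n_sd = 2) {
  rule <- match.arg(rule)
  if (is.null(group)) group <- rep(1L, length(values))
  keep <- rep(TRUE, length(values))
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- values[idx]
    if (length(v) < 3L) {
      warning("group with fewer than 3 values: all kept", call. = FALSE)
      next
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("degenerate group (SD = 0): all kept", call. = FALSE)
      next
    }
    m <- mean(v)
    keep[idx] <- if (rule == "two_sided") {
      abs(v - m) <= n_sd * s
    } else {
      v >= m - n_sd * s
    }
  }
  keep
}
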