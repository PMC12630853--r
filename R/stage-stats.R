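# Rank-based stage statistics: Friedman/Kendall's W, Dunn post-hoc with
# Cliff's delta, Wilcoxon signed-rank with rank-biserial correlation,
# partial Spearman correlation controlling for stage, quartile courses,
# and chronological epoch regression.

kendall_w_bands <- function(w) {
  if (w <= 0.2) "slight" else if (w <= 0.4) "fair" else
    if (w <= 0.6) "moderate" else if (w <= 0.8) "substantial" else
      "almost perfect"
}

#' Friedman test with Kendall's W effect size
#'
#' `W = X^2 / (N * (K - 1))`, where `N` is the number of subjects (rows)
#' and `K` the number of conditions (columns). Ties are handled by
#' midranks; W lies in [0, 1] with 1 for perfectly concordant rankings.
#'
#' @param m Complete subjects-by-conditions numeric matrix, `K >= 3`.
#' @return A list of class `stat_result` with `test`, `statistic` (X^2),
#'   `df`, `p`, `effect` (W), `effect_label`, `n`, `k`.
#' @export
friedman_kendall <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stopf("matrix must be complete")
  if (ncol(m) < 3L) stopf("need K >= 3 conditions")
  n <- nrow(m)
  k <- ncol(m)
  all_tied <- apply(m, 1L, function(r) length(unique(r)) == 1L)
  if (any(all_tied)) {
    warning(sprintf("%d all-tied row(s)", sum(all_tied)), call. = FALSE)
  }
  if (all(all_tied)) {
    # fully degenerate matrix: no concordance information
    return(structure(list(test = "friedman", statistic = 0,
                          df = k - 1, p = 1, effect = 0,
                          effect_label = kendall_w_bands(0),
                          n = n, k = k),
                     class = "stat_result"))
  }
  ft <- stats::friedman.test(m)
  x2 <- unname(ft$statistic)
  w <- x2 / (n * (k - 1))
  structure(list(test = "friedman", statistic = x2,
                 df = unname(ft$parameter), p = ft$p.value,
                 effect = w, effect_label = kendall_w_bands(w),
                 n = n, k = k),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic=%.4g, p=%.4g, effect=%.4g (%s)\n",
              x$test, x$statistic, x$p, x$effect,
              if (!is.null(x$effect_label)) x$effect_label else ""))
  invisible(x)
}

#' Cliff's delta with normal-approximation confidence interval
#'
#' `cd = 2p - 1` where `p` is the dominance probability that a value of
#' `a` exceeds a value of `b` over all `n1 * n2` pairs (ties count 0.5).
#' The 95% CI uses `SEp = sqrt(p * (1 - p) / (n1 * n2))`, the interval
#' `p +/- 1.96 * SEp` transformed back and clipped to [-1, 1].
#'
#' @param a,b Numeric vectors.
#' @return A list with `delta`, `ci` (length 2), `p_dom`.
#' @export
cliffs_delta <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 * n2 == 0) stopf("both groups must be non-empty")
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  p <- sum(cmp) / (n1 * n2)
  se <- sqrt(p * (1 - p) / (n1 * n2))
  ci_p <- p + c(-1.96, 1.96) * se
  list(delta = 2 * p - 1,
       ci = pmin(pmax(2 * ci_p - 1, -1), 1),
       p_dom = p)
}

#' Dunn's post-hoc test after a Friedman test
#'
#' Pairwise z statistics from mean within-subject rank differences,
#' `z = (Rbar_i - Rbar_j) / sqrt(K * (K + 1) / (6 * N))`, with Bonferroni
#' correction over all pairs, plus Cliff's delta (with clipped CI) per
#' pair.
#'
#' @param m Complete subjects-by-conditions matrix (same input as
#'   [friedman_kendall()]).
#' @param correction Only `"bonferroni"` is supported.
#' @return A [tibble::tibble] with columns `a`, `b`, `z`, `p_bonf`,
#'   `cliffs_delta`, `ci_lo`, `ci_hi`.
#' @export
dunn_posthoc <- function(m, correction = "bonferroni") {
  stopifnot(correction == "bonferroni")
  m <- as.matrix(m)
  if (anyNA(m)) stopf("matrix must be complete")
  n <- nrow(m)
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(k))
  ranks <- t(apply(m, 1L, rank))  # midranks within subject
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(pi) {
    i <- pairs[1, pi]
    j <- pairs[2, pi]
    z <- (rbar[i] - rbar[j]) / se
    p <- min(1, 2 * stats::pnorm(-abs(z)) * n_pairs)
    cd <- cliffs_delta(m[, i], m[, j])
    tibble::tibble(a = colnames(m)[i], b = colnames(m)[j],
                   z = unname(z), p_bonf = p,
                   cliffs_delta = cd$delta, ci_lo = cd$ci[1],
                   ci_hi = cd$ci[2])
  })
  do.call(rbind, rows)
}

#' Wilcoxon signed-rank test with rank-biserial correlation
#'
#' Paired test; `W` is the positive-rank sum and the effect size is
#' `r = (W+ - W-) / (W+ + W-)`.
#'
#' @param a,b Paired numeric vectors of equal length with at least 5
#'   non-zero differences.
#' @return A `stat_result` list with `statistic` (W+), `p` (two-sided),
#'   `effect` (rank-biserial r), `n_nonzero`.
#' @export
wilcoxon_rank_biserial <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) < 5L) stopf("need >= 5 non-zero differences")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  wt <- suppressWarnings(stats::wilcox.test(d, exact = length(d) < 50))
  structure(list(test = "wilcoxon_signed_rank", statistic = w_pos,
                 p = wt$p.value,
                 effect = (w_pos - w_neg) / (w_pos + w_neg),
                 effect_label = NULL, n_nonzero = length(d)),
            class = "stat_result")
}

#' Partial Spearman correlation controlling for sleep stage
#'
#' Rank-transforms `x` and `y`, regresses each on stage indicator
#' variables, and correlates the residuals. The 95% CI uses the Fisher-z
#' approximation with the residual degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param control Factor-like vector of stage labels (the confound).
#' @return A list with `rho`, `p`, `ci`, `df`.
#' @export
partial_spearman <- function(x, y, control) {
  n <- length(x)
  if (n < 10L) stopf("need >= 10 observations")
  control <- factor(control)
  if (nlevels(control) < 2L) {
    warning("single stage present; plain Spearman returned", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    rho <- unname(ct$estimate)
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    return(list(rho = rho, p = ct$p.value,
                ci = tanh(z + c(-1.96, 1.96) * se), df = n - 2))
  }
  rx <- rank(x)
  ry <- rank(y)
  ex <- stats::resid(stats::lm(rx ~ control))
  ey <- stats::resid(stats::lm(ry ~ control))
  rho <- stats::cor(ex, ey)
  df <- n - 2L - (nlevels(control) - 1L)
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df)
  z <- atanh(rho)
  se <- 1 / sqrt(n - 3 - (nlevels(control) - 1L))
  list(rho = rho, p = p, ci = tanh(z + c(-1.96, 1.96) * se), df = df)
}

#' Quartile course of a stage-specific feature across the night
#'
#' Splits each subject's epochs, per sleep stage, into chronological
#' quartiles (ties to the earlier quartile), averages the feature per
#' quartile, and runs a Friedman test across quartiles per stage.
#' Subject-stage cells with fewer than 4 epochs are dropped.
#'
#' @param table Data frame with columns `subject`, `stage`,
#'   `epoch_index`, `value`.
#' @return A list with `quartile_means` (tibble: subject, stage, q1-q4)
#'   and `tests` (per-stage `stat_result`s, stages with >= 3 complete
#'   subjects).
#' @export
quartile_course <- function(table) {
  table <- as.data.frame(table)
  need <- c("subject", "stage", "epoch_index", "value")
  if (!all(need %in% names(table))) {
    stopf("`table` needs columns %s", paste(need, collapse = ", "))
  }
  rows <- list()
  for (subj in unique(table$subject)) {
    for (st in unique(table$stage)) {
      v <- table[table$subject == subj & table$stage == st, ]
      if (nrow(v) < 4L) next
      v <- v[order(v$epoch_index), ]
      # chronological quartiles, ties to the earlier quartile
      q <- ceiling(seq_len(nrow(v)) / (nrow(v) / 4))
      q <- pmin(q, 4L)
      means <- tapply(v$value, q, mean)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subj, stage = st,
        q1 = means[["1"]], q2 = means[["2"]], q3 = means[["3"]],
        q4 = means[["4"]])
    }
  }
  if (!length(rows)) stopf("no subject-stage cell has >= 4 epochs")
  qm <- do.call(rbind, rows)
  tests <- list()
  for (st in unique(qm$stage)) {
    sub <- qm[qm$stage == st, ]
    if (nrow(sub) < 3L) next
    tests[[st]] <- friedman_kendall(as.matrix(sub[, c("q1", "q2", "q3", "q4")]))
  }
  list(quartile_means = qm, tests = tests)
}

#' Chronological regression of epoch-wise values
#'
#' Ordinary least squares of the feature on chronological epoch index,
#' reporting R^2, the F statistic, its p-value and the slope.
#'
#' @param values Numeric vector of epoch-wise values in chronological
#'   order (>= 5).
#' @return A list with `r_squared`, `f`, `df`, `p`, `slope`,
#'   `intercept`.
#' @export
epoch_regression <- function(values) {
  if (length(values) < 5L) stopf("need >= 5 epochs")
  if (stats::sd(values) == 0) stopf("constant values: regression undefined")
  idx <- seq_along(values)
  fit <- stats::lm(values ~ idx)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       f = unname(s$fstatistic[1]),
       df = unname(s$fstatistic[2:3]),
       p = stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
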