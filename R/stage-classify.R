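# Sleep-stage classification: LDA with stratified repeated K-fold CV,
# permutation t-tests of accuracies against chance, and random-forest
# permutation feature importance.

# Stratified fold assignment: per class, shuffled indices dealt round-robin
# into n_folds folds. Returns an integer fold id per row.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' LDA sleep-stage classification with repeated stratified K-fold CV
#'
#' Equalizes the number of trials per stage by seeded random subsampling,
#' then runs stratified K-fold cross-validation (default 5 splits, 2
#' repetitions: train on 80%, test on 20%). When a `group` column is
#' supplied, groups with fewer than `min_trials` trials in any stage are
#' dropped (and named in the result) and classification is run per group.
#'
#' @param table Data frame with a `stage` column and feature columns.
#' @param features Character vector of feature column names.
#' @param group Optional name of a grouping column (e.g. region); `NULL`
#'   pools everything.
#' @param n_folds,n_rep Cross-validation structure (defaults 5, 2).
#' @param min_trials Minimum trials per stage per group (default 25;
#'   applied only when `group` is given).
#' @param seed Integer seed for equalization and fold assignment.
#' @return A list of class `classification_result`: `fold_accuracies`,
#'   `mean_accuracy`, `chance` (= 1/n_classes), `n_classes`,
#'   `n_per_class`, `dropped_groups`.
#' @export
lda_stage_classification <- function(table, features, group = NULL,
                                     n_folds = 5, n_rep = 2,
                                     min_trials = 25, seed = 1) {
  table <- as.data.frame(table)
  if (!"stage" %in% names(table)) stopf("`table` needs a `stage` column")
  if (!all(features %in% names(table))) stopf("missing feature column(s)")
  if (any(!is.finite(as.matrix(table[features])))) {
    stopf("features must be finite (apply exclusion_filters first)")
  }
  dropped <- character(0)
  if (!is.null(group)) {
    counts <- table(table[[group]], table$stage)
    bad <- rownames(counts)[apply(counts, 1L, min) < min_trials]
    dropped <- bad
    table <- table[!(table[[group]] %in% bad), , drop = FALSE]
    if (!nrow(table)) stopf("no groups meet the minimum trial count")
  }
  stages <- unique(table$stage)
  if (length(stages) < 2L) stopf("need >= 2 stages for classification")
  accs <- with_seed(seed, {
    # equalize trials per stage by random subsampling
    n_min <- min(table(table$stage))
    idx <- unlist(lapply(stages, function(s) {
      sample(which(table$stage == s), n_min)
    }))
    dat <- table[idx, , drop = FALSE]
    y <- factor(dat$stage)
    x <- as.matrix(dat[features])
    out <- numeric(0)
    for (rep_i in seq_len(n_rep)) {
      folds <- stratified_folds(as.character(y), n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < length(levels(y))) {
          stopf("a class is absent from a training fold")
        }
        fit <- MASS::lda(x[tr, , drop = FALSE], grouping = y[tr])
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])$class
        out <- c(out, mean(pred == y[!tr]))
      }
    }
    out
  })
  structure(list(fold_accuracies = accs, mean_accuracy = mean(accs),
                 chance = 1 / length(stages),
                 n_classes = length(stages),
                 n_per_class = min(table(table$stage)),
                 dropped_groups = dropped),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> mean accuracy %.3f over %d folds (chance %.3f, %d classes)\n",
    x$mean_accuracy, length(x$fold_accuracies), x$chance, x$n_classes))
  invisible(x)
}

#' Permutation t-test of accuracies against chance level
#'
#' Builds a chance array of the same length as the observations,
#' concatenates both, shuffles the labels, splits, and computes a t-test
#' per permutation; the two-sided p-value is the proportion of permuted
#' |t| at or above the observed |t| (resolution 1/n_perm), multiplied by
#' the Bonferroni `family` size supplied by the caller.
#'
#' @param accuracies Numeric vector of per-fold accuracies (>= 3).
#' @param chance Chance level (e.g. 0.2 for five classes).
#' @param n_perm Number of permutations (default 10000).
#' @param family Bonferroni family size (default 1; always explicit).
#' @param seed Integer seed.
#' @return A list with `t`, `p`, `p_bonf`, `cohens_d`
#'   (`(mean - chance)/SD`), `n_perm`.
#' @export
permutation_ttest_vs_chance <- function(accuracies, chance, n_perm = 10000,
                                        family = 1, seed = 1) {
  if (length(accuracies) < 3L) stopf("need >= 3 accuracy values")
  n <- length(accuracies)
  comb <- c(accuracies, rep(chance, n))
  t_of <- function(a, b) {
    sp <- sqrt(((n - 1) * stats::var(a) + (n - 1) * stats::var(b)) /
                 (2 * n - 2))
    if (sp == 0) return(0)
    (mean(a) - mean(b)) / (sp * sqrt(2 / n))
  }
  s <- stats::sd(accuracies)
  if (s == 0) {
    # analytic fallback: no variance -> degenerate, report exact mean diff
    warning("zero variance in accuracies; analytic fallback", call. = FALSE)
    p <- if (mean(accuracies) == chance) 1 else 1 / n_perm
    return(list(t = Inf * sign(mean(accuracies) - chance), p = p,
                p_bonf = min(1, p * family),
                cohens_d = Inf * sign(mean(accuracies) - chance),
                n_perm = n_perm))
  }
  t_obs <- t_of(accuracies, comb[(n + 1):(2 * n)])
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sh <- sample(comb)
      t_of(sh[1:n], sh[(n + 1):(2 * n)])
    }, numeric(1))
  })
  p <- max(mean(abs(t_perm) >= abs(t_obs)), 1 / n_perm)
  list(t = t_obs, p = p, p_bonf = min(1, p * family),
       cohens_d = (mean(accuracies) - chance) / s, n_perm = n_perm)
}

#' Random-forest permutation feature importance
#'
#' For each feature, fits single-predictor random forests (default 100
#' trees) under K-fold cross-validation and measures importance as the
#' mean drop in held-out accuracy when that feature is permuted
#' (default 1000 shuffles), addressing collinearity by considering one
#' predictor at a time.
#'
#' @param table Data frame with `stage` and feature columns.
#' @param features Character vector of feature names (>= 1).
#' @param n_trees Number of trees (default 100).
#' @param n_folds CV folds (default 5).
#' @param n_shuffle Permutation repetitions (default 1000).
#' @param seed Integer seed.
#' @return A [tibble::tibble] with columns `feature`, `importance`,
#'   `sem`.
#' @export
rf_feature_importance <- function(table, features, n_trees = 100,
                                  n_folds = 5, n_shuffle = 1000, seed = 1) {
  table <- as.data.frame(table)
  if (any(!is.finite(as.matrix(table[features])))) {
    stopf("features must be finite")
  }
  y <- factor(table$stage)
  with_seed(seed, {
    rows <- lapply(features, function(feat) {
      x <- table[[feat]]
      if (stats::sd(x) == 0) {
        # permuting a constant cannot change predictions
        return(tibble::tibble(feature = feat, importance = 0, sem = 0))
      }
      folds <- stratified_folds(as.character(y), n_folds)
      drops <- numeric(0)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        fit <- randomForest::randomForest(
          x = data.frame(v = x[tr]), y = y[tr], ntree = n_trees)
        te <- data.frame(v = x[!tr])
        base_acc <- mean(stats::predict(fit, te) == y[!tr])
        for (s in seq_len(n_shuffle)) {
          perm <- data.frame(v = sample(te$v))
          drops <- c(drops,
                     base_acc - mean(stats::predict(fit, perm) == y[!tr]))
        }
      }
      tibble::tibble(feature = feat, importance = mean(drops),
                     sem = stats::sd(drops) / sqrt(length(drops)))
    })
    do.call(rbind, rows)
  })
}
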