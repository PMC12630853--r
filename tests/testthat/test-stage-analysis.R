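# Stage-level statistics and classification, checked against brute-force
# oracles on small instances.

test_that("LDA classification separates separable classes and stays at
           chance on shuffled labels", {
  set.seed(1)
  n <- 200
  tab <- data.frame(
    stage = rep(c("N2", "N3"), each = n),
    f1 = c(rnorm(n, 0), rnorm(n, 10)),
    f2 = c(rnorm(n, 0), rnorm(n, 10)))
  res <- lda_stage_classification(tab, c("f1", "f2"), seed = 2)
  expect_gte(res$mean_accuracy, 0.99)
  expect_equal(res$chance, 0.5)

  set.seed(3)
  tab5 <- data.frame(stage = sample(sleep_stages(), 500, replace = TRUE),
                     f1 = rnorm(500))
  res5 <- lda_stage_classification(tab5, "f1", seed = 4)
  expect_equal(res5$chance, 0.2)
  # within the binomial 95% CI of 0.2 for the pooled test trials
  n_test <- res5$n_per_class * 5 * 2  # every trial tested twice
  expect_lt(abs(res5$mean_accuracy - 0.2),
            1.96 * sqrt(0.2 * 0.8 / n_test) + 0.02)
})

test_that("groups under the minimum trial count are dropped", {
  set.seed(5)
  tab <- data.frame(
    stage = rep(rep(c("N2", "N3"), each = 30), 2),
    region = rep(c("A", "B"), each = 60),
    f1 = rnorm(120))
  tab <- tab[-(61:66), ]  # region B now has 24 N2 trials
  res <- lda_stage_classification(tab, "f1", group = "region", seed = 6)
  expect_equal(res$dropped_groups, "B")
})

test_that("permutation t-test against chance behaves at the extremes", {
  set.seed(7)
  at_chance <- rnorm(10, 0.2, 0.02)
  at_chance <- at_chance - mean(at_chance) + 0.2
  r0 <- permutation_ttest_vs_chance(at_chance, 0.2, n_perm = 1000,
                                    seed = 8)
  expect_gt(r0$p, 0.5)

  far <- rnorm(10, 0.2, 0.001) + 10 * 0.001 + 0.5
  r1 <- permutation_ttest_vs_chance(far, 0.2, n_perm = 1000, seed = 9)
  expect_equal(r1$p, 1 / 1000)  # permutation resolution floor
  expect_gt(r1$cohens_d, 10)
  # Bonferroni family is explicit and capped at 1
  r2 <- permutation_ttest_vs_chance(at_chance, 0.2, n_perm = 200,
                                    family = 3, seed = 8)
  expect_lte(r2$p_bonf, 1)
  expect_equal(r2$p_bonf, min(1, r2$p * 3))
  expect_error(permutation_ttest_vs_chance(c(0.5, 0.6), 0.2), ">= 3")
})

test_that("random-forest permutation importance ranks informative
           features", {
  set.seed(10)
  n <- 150
  stage <- sample(c("N2", "N3"), n, replace = TRUE)
  tab <- data.frame(
    stage = stage,
    informative = ifelse(stage == "N2", 0, 3) + rnorm(n, 0, 0.5),
    noise = rnorm(n),
    constant = rep(1, n))
  imp <- rf_feature_importance(tab, c("informative", "noise", "constant"),
                               n_shuffle = 50, seed = 11)
  v <- setNames(imp$importance, imp$feature)
  expect_gt(v[["informative"]], v[["noise"]] + 0.2)
  expect_lt(abs(v[["constant"]]), 0.02)
  imp2 <- rf_feature_importance(tab, c("informative", "noise", "constant"),
                                n_shuffle = 50, seed = 11)
  expect_identical(imp, imp2)  # seeded determinism
})

test_that("Friedman/Kendall W matches brute force and its extremes", {
  # perfectly concordant rankings: X2 = N(K-1), W = 1
  m <- matrix(rep(c(1, 5, 9, 13), each = 6), nrow = 6) +
    matrix(rnorm(24, 0, 0.01), nrow = 6)
  r <- friedman_kendall(m)
  expect_equal(r$statistic, 6 * 3, tolerance = 1e-10)
  expect_equal(r$effect, 1, tolerance = 1e-10)
  expect_equal(r$effect_label, "almost perfect")

  # toy integer table vs first-principles rank computation
  toy <- matrix(c(1, 2, 3,
                  2, 3, 1,
                  1, 3, 2), nrow = 3, byrow = TRUE)
  bf <- brute_friedman(toy)
  rt <- friedman_kendall(toy)
  expect_equal(rt$statistic, bf$x2, tolerance = 1e-10)
  expect_equal(rt$effect, bf$w, tolerance = 1e-10)

  # independently shuffled rows: near-zero concordance
  set.seed(12)
  shuf <- t(replicate(50, sample(4)))
  expect_lt(friedman_kendall(shuf)$effect, 0.1)

  # random integer matrices with ties agree with the brute-force oracle
  set.seed(13)
  for (i in 1:25) {
    mm <- matrix(sample(1:3, 9, replace = TRUE), 3)
    if (any(apply(mm, 1, function(r) length(unique(r)) == 1))) next
    bfi <- brute_friedman(mm)
    ri <- suppressWarnings(friedman_kendall(mm))
    expect_equal(ri$statistic, bfi$x2, tolerance = 1e-10)
    expect_equal(ri$effect, bfi$w, tolerance = 1e-10)
  }
  expect_error(friedman_kendall(matrix(1:4, 2)), "K >= 3")
})

test_that("Dunn post-hoc z and Cliff's delta match brute force", {
  set.seed(14)
  m <- cbind(a = rnorm(8, 0), b = rnorm(8, 1), c = rnorm(8, 3))
  res <- dunn_posthoc(m)
  # z from first principles: mean within-row rank differences
  ranks <- t(apply(m, 1, rank))
  se <- sqrt(3 * 4 / (6 * 8))
  z_ab <- (mean(ranks[, 1]) - mean(ranks[, 2])) / se
  expect_equal(res$z[res$a == "a" & res$b == "b"], z_ab,
               tolerance = 1e-10)
  # Cliff's delta against pair enumeration
  for (i in seq_len(nrow(res))) {
    expect_equal(res$cliffs_delta[i],
                 brute_cliffs(m[, res$a[i]], m[, res$b[i]]),
                 tolerance = 1e-10)
  }
  # identical groups: delta 0, CI spanning 0
  cd0 <- cliffs_delta(m[, 1], m[, 1])
  expect_equal(cd0$delta, 0)
  expect_lte(cd0$ci[1], 0)
  expect_gte(cd0$ci[2], 0)
  # full separation: delta 1 with the CI clipped at 1
  cd1 <- cliffs_delta(11:14, 1:4)
  expect_equal(cd1$delta, 1)
  expect_equal(cd1$ci[2], 1)
  # toy 4-element groups with a tie
  expect_equal(cliffs_delta(c(1, 2, 3, 4), c(2, 2, 0, 0))$delta,
               brute_cliffs(c(1, 2, 3, 4), c(2, 2, 0, 0)))
  # antisymmetry over random pairs
  set.seed(15)
  for (i in 1:10) {
    a <- sample(1:5, 6, replace = TRUE)
    b <- sample(1:5, 6, replace = TRUE)
    expect_equal(cliffs_delta(a, b)$delta, -cliffs_delta(b, a)$delta,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon signed-rank W and rank-biserial r match an exhaustive
           oracle", {
  a <- c(5.1, 4.8, 6.0, 5.5, 4.9, 5.7)
  b <- c(4.6, 4.9, 5.1, 5.0, 4.4, 5.2)
  d <- a - b
  r_abs <- rank(abs(d))
  w_pos <- sum(r_abs[d > 0])
  res <- wilcoxon_rank_biserial(a, b)
  expect_equal(res$statistic, w_pos)
  expect_equal(res$effect,
               (w_pos - sum(r_abs[d < 0])) / sum(r_abs))
  # a uniformly greater than b: r = 1
  expect_equal(wilcoxon_rank_biserial(2:11, 1:10)$effect, 1)
  expect_error(wilcoxon_rank_biserial(1:10, 1:10), "non-zero")
})

test_that("partial Spearman controls for the stage confound", {
  set.seed(16)
  n <- 120
  stage <- rep(c("N2", "N3", "REM"), each = n / 3)
  # stage-independent association: partial ~ plain
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 0.3)
  p1 <- partial_spearman(x, y, stage)
  plain <- cor(x, y, method = "spearman")
  expect_lt(abs(p1$rho - plain), 0.1)
  expect_lt(p1$p, 1e-6)

  # pure stage confound: plain correlation large, partial near zero
  mu <- c(N2 = 0, N3 = 3, REM = 6)[stage]
  x2 <- mu + rnorm(n, 0, 0.5)
  y2 <- mu + rnorm(n, 0, 0.5)
  p2 <- partial_spearman(x2, y2, stage)
  expect_gt(cor(x2, y2, method = "spearman"), 0.7)
  expect_lt(abs(p2$rho), 0.2)

  # exact inverse relation
  expect_equal(partial_spearman(1:20, -(1:20),
                                rep(c("a", "b"), 10))$rho, -1,
               tolerance = 1e-10)
  expect_warning(partial_spearman(rnorm(12), rnorm(12),
                                  rep("N2", 12)), "single stage")
})

test_that("quartile course splits chronologically and flags drift", {
  # 8 epochs -> quartiles of 2
  tab <- data.frame(subject = 1, stage = "N2", epoch_index = 1:8,
                    value = c(1, 3, 2, 4, 5, 7, 6, 8))
  qc <- suppressWarnings(quartile_course(tab))
  expect_equal(unlist(qc$quartile_means[1, c("q1", "q2", "q3", "q4")]),
               c(q1 = 2, q2 = 3, q3 = 6, q4 = 7))

  # linear drift across epochs: monotone quartile means, significant
  # Friedman at 17 subjects
  set.seed(17)
  drift <- do.call(rbind, lapply(1:17, function(s) {
    data.frame(subject = s, stage = "REM", epoch_index = 1:40,
               value = 0.02 * (1:40) + rnorm(40, 0, 0.1))
  }))
  qc2 <- quartile_course(drift)
  qm <- colMeans(qc2$quartile_means[, c("q1", "q2", "q3", "q4")])
  expect_true(all(diff(qm) > 0))
  expect_lt(qc2$tests$REM$p, 0.05)

  # constant epochs: zero concordance
  const <- data.frame(subject = rep(1:5, each = 8), stage = "N2",
                      epoch_index = rep(1:8, 5), value = 1)
  qc3 <- suppressWarnings(quartile_course(const))
  expect_lt(qc3$tests$N2$effect, 1e-10)
})

test_that("epoch regression reports OLS R2, F, p and slope", {
  r <- suppressWarnings(epoch_regression(2 + 0.5 * (1:30)))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)

  # null calibration: p uniform under white noise
  set.seed(18)
  ps <- replicate(500, epoch_regression(rnorm(100))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.05)

  # slope recovery within the 95% CI in ~95% of seeds
  set.seed(19)
  hits <- mean(replicate(100, {
    v <- 0.01 * (1:130) + rnorm(130, 0, 0.1)
    fit <- lm(v ~ seq_along(v))
    ci <- confint(fit)[2, ]
    ci[1] <= 0.01 && 0.01 <= ci[2]
  }))
  expect_gte(hits, 0.87)
  expect_error(epoch_regression(rep(1, 10)), "constant")
})
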