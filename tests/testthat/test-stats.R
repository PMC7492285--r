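test_that("matched-pairs Wilcoxon uses the exact signed-rank distribution", {
  expect_equal(wilcoxon_matched(1:5, 1:5)$p_value, 1)
  expect_true(wilcoxon_matched(1:5, 1:5)$degenerate)
  # n = 6, all differences positive: exact p = 2 / 2^6
  pre <- rep(0, 6); post <- c(1, 2, 3, 4, 5, 6)
  expect_equal(wilcoxon_matched(pre, post)$p_value, 2 / 64)
  # exact p equals full 2^n enumeration on random untied data
  set.seed(3)
  for (i in 1:5) {
    d <- rnorm(10)
    res <- wilcoxon_matched(rep(0, 10), d)
    expect_equal(res$p_value, wilcoxon_enum_p(d))
    expect_true(res$details$exact)
  }
  # ties fall back to the tie-corrected normal approximation
  res_tied <- wilcoxon_matched(rep(0, 30), c(rep(1, 15), rep(-2, 15)))
  expect_false(res_tied$details$exact)
  expect_true(res_tied$p_value >= 0 && res_tied$p_value <= 1)
})

test_that("paired t matches the closed form and flags zero variance", {
  expect_true(paired_t(c(1, 2, 3), c(1, 2, 3))$degenerate)
  expect_true(paired_t(c(0, 0, 0, 0), c(1, 1, 1, 1))$degenerate)
  d <- c(2, -1, 3, 0, 1)
  res <- paired_t(rep(0, 5), d)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df = 4))
})

test_that("Friedman + Dunn behave on degenerate, extreme and swapped data", {
  x <- matrix(5, 6, 3, dimnames = list(NULL, c("delta0", "delta1", "delta2")))
  fd <- friedman_dunn(x)
  expect_equal(fd$overall$statistic, 0)
  expect_equal(fd$overall$p_value, 1)
  # strictly decreasing across loads for every sample: maximal statistic
  set.seed(4)
  y <- t(replicate(8, sort(runif(3), decreasing = TRUE)))
  colnames(y) <- c("delta0", "delta1", "delta2")
  fd2 <- friedman_dunn(y)
  expect_equal(fd2$overall$statistic, 16) # n * (k - 1) for perfect ordering
  # Dunn results are symmetric under column swap
  y2 <- y[, c(2, 1, 3)]
  fd3 <- friedman_dunn(y2)
  z12 <- fd2$pairwise$z[fd2$pairwise$comparison == "delta0 vs delta1"]
  z21 <- fd3$pairwise$z[fd3$pairwise$comparison == "delta1 vs delta0"]
  expect_equal(z12, -z21)
  expect_equal(sort(fd2$pairwise$p_adj), sort(fd3$pairwise$p_adj))
  # incomplete triples are dropped and counted
  y3 <- rbind(y, c(NA, 1, 2))
  expect_equal(friedman_dunn(y3)$n_dropped, 1)
})

test_that("repeated-measures ANOVA matches hand-partitioned sums of squares", {
  x <- matrix(c(10, 12, 14,
                11, 14, 17,
                9, 11, 16), nrow = 3, byrow = TRUE)
  res <- rm_anova(x)
  # closed-form within-subject one-way partition
  n <- 3; k <- 3
  grand <- mean(x)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_hand <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$statistic, f_hand)
  expect_equal(res$p_value, stats::pf(f_hand, k - 1, (n - 1) * (k - 1),
                                      lower.tail = FALSE))
  # location invariance and degeneracy
  expect_equal(rm_anova(x + 100)$statistic, res$statistic)
  expect_true(rm_anova(matrix(3, 4, 3))$degenerate)
})

test_that("Holm adjustment is the hand-computed step-down", {
  expect_equal(holm_adjust(0.37)$adjusted, 0.37)
  res <- holm_adjust(c(0.001, 0.02, 0.03), alpha = 0.01)
  expect_equal(res$adjusted, c(0.003, 0.04, 0.04))
  expect_equal(res$reject, c(TRUE, FALSE, FALSE))
  # adjusted p values are non-decreasing in the sorted order
  set.seed(5)
  p <- runif(20)
  adj <- holm_adjust(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # Holm dominance: every Bonferroni rejection is a Holm rejection
  for (i in 1:20) {
    p <- runif(15)^3
    m <- length(p)
    bonf <- p <= 0.01 / m
    holm <- holm_adjust(p, alpha = 0.01)$reject
    expect_true(all(holm[bonf]))
  }
})

test_that("report tables carry group cells, raw and Holm-adjusted p values", {
  set.seed(6)
  grid <- tidyr::expand_grid(
    sample_id = sprintf("s%d", 1:8), arm = "control",
    modality = c("T1rho_SL", "T2_SE"), roi = roi_names(),
    session = c("pre", "post"), load_level = c("delta0", "delta1", "delta2"))
  base <- 60
  eff <- ifelse(grid$session == "post" & grid$modality == "T1rho_SL", 0.88, 1)
  grid$mean <- base * eff * (1 + rnorm(nrow(grid), 0, 0.01))
  grid$n_valid <- 20L
  deltas <- build_delta_records(grid)
  tabs <- study_tables(grid, deltas, alpha = 0.01)
  t1 <- tabs$table1
  expect_equal(nrow(t1), 2 * 7)
  row <- t1[t1$modality == "T1rho_SL" & t1$roi == "ECS", ]
  expect_lt(abs(row$mean - (-12)), 2)
  expect_true(row$p_holm >= row$p_raw || row$p_holm == row$p_raw)
  expect_true(all(t1$p_holm >= t1$p_raw - 1e-15, na.rm = TRUE))
  t2 <- tabs$table2
  expect_equal(nrow(t2), 2 * 7)
  expect_true(all(c("delta_1_pre_mean", "delta_2_post_sd",
                    "p_holm_delta1", "significant_delta2") %in% names(t2)))
  # two-point cells: mean present, SD from two values
  mini <- deltas[deltas$sample_id %in% c("s1", "s2"), ]
  mini_sum <- grid[grid$sample_id %in% c("s1", "s2"), ]
  tt <- study_tables(mini_sum, mini, alpha = 0.01)$table1
  expect_true(all(is.finite(tt$mean)))
})
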