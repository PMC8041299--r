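test_that("balanced ANOVA reproduces the brute-force SS decomposition", {
  set.seed(81)
  d <- make_design(4L)
  for (rep in 1:10) {
    y <- rnorm(nrow(d)) +
      rnorm(nlevels(d$diet))[as.integer(d$diet)] * runif(1, 0, 2) +
      c(0, runif(1, 0, 2))[as.integer(d$stage)]
    av <- two_way_anova(y, d$diet, d$stage)
    bf <- brute_force_anova_ss(y, d$diet, d$stage)
    expect_equal(av$table["diet", "Sum Sq"], bf[["diet"]],
                 tolerance = 1e-8)
    expect_equal(av$table["stage", "Sum Sq"], bf[["stage"]],
                 tolerance = 1e-8)
    expect_equal(av$table["diet:stage", "Sum Sq"], bf[["interaction"]],
                 tolerance = 1e-8)
    expect_equal(av$table["Residuals", "Sum Sq"], bf[["error"]],
                 tolerance = 1e-8)
    # exact partition for balanced data
    expect_equal(sum(av$table[, "Sum Sq"]), sum((y - mean(y))^2),
                 tolerance = 1e-8)
  }
})

test_that("degenerate constant data yields NA p-values with a flag", {
  d <- make_design(2L)
  av <- two_way_anova(rep(3.7, nrow(d)), d$diet, d$stage)
  expect_true(av$degenerate)
  expect_true(is.na(av$p_diet) && is.na(av$p_stage) &&
                is.na(av$p_interaction))
})

test_that("design errors are caught and named", {
  d <- make_design(2L)
  drop_idx <- which(d$diet == "D0_FO" & d$stage == "FW")
  expect_error(two_way_anova(rnorm(nrow(d) - length(drop_idx)),
                             d$diet[-drop_idx], d$stage[-drop_idx]),
               "empty design cell|unbalanced")
  expect_error(two_way_anova(rnorm(nrow(d) - 1), d$diet[-1], d$stage[-1]),
               "unbalanced")
})

test_that("a planted stage effect of 2 sd is detected with high power", {
  set.seed(82)
  d <- make_design(4L)
  hits <- vapply(1:200, function(i) {
    y <- rnorm(nrow(d)) + 2 * (d$stage == "SW")
    two_way_anova(y, d$diet, d$stage)$p_stage < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("Tukey p agrees with TukeyHSD on the 16-cell family", {
  set.seed(83)
  d <- make_design(4L)
  y <- rnorm(nrow(d)) + as.integer(d$diet) * 0.3 +
    2 * (d$stage == "SW")
  av <- two_way_anova(y, d$diet, d$stage)
  cellf <- interaction(d$diet, d$stage, sep = ":")
  th <- TukeyHSD(aov(y ~ cellf))$cellf
  cm <- tapply(y, cellf, mean)
  pair <- c("D0_FO:SW", "D0_FO:FW")
  mine <- tukey_hsd_p(cm[pair[1]], cm[pair[2]], av$mse, av$df_error, 4L,
                      k_family = 16L)
  row <- th[rownames(th) %in% c(paste(pair, collapse = "-"),
                                paste(rev(pair), collapse = "-")), ]
  expect_equal(unname(mine), unname(row["p adj"]), tolerance = 1e-8)
})

test_that("Tukey adjustment respects published studentized-range critical values", {
  # k = 3 groups, n = 4 each, df = 9: q_{0.05}(3, 9) = 3.948 (standard table)
  q_crit <- qtukey(0.95, nmeans = 3, df = 9)
  expect_equal(q_crit, 3.948, tolerance = 1e-3)
  mse <- 1.3; n <- 4
  delta_at_crit <- q_crit * sqrt(mse / n)
  expect_equal(tukey_hsd_p(delta_at_crit, 0, mse, 9, n, k_family = 3), 0.05,
               tolerance = 1e-8)
  expect_lt(tukey_hsd_p(delta_at_crit * 1.2, 0, mse, 9, n, k_family = 3),
            0.05)
  expect_gt(tukey_hsd_p(delta_at_crit * 0.8, 0, mse, 9, n, k_family = 3),
            0.05)
  # identical cell means: p = 1
  expect_equal(tukey_hsd_p(2.5, 2.5, mse, 9, n), 1, tolerance = 1e-12)
})

test_that("Tukey p dominates the unadjusted pairwise p and grows with k", {
  set.seed(84)
  for (rep in 1:50) {
    mse <- runif(1, 0.5, 3); df <- sample(16:48, 1); n <- 4L
    m1 <- rnorm(1); m2 <- m1 + runif(1, 0, 2)
    p_raw <- 2 * pt(-abs(m1 - m2) / sqrt(2 * mse / n), df)
    p_t <- vapply(c(2L, 4L, 8L, 16L), function(k)
      tukey_hsd_p(m1, m2, mse, df, n, k_family = k), 0)
    expect_true(all(diff(p_t) >= -1e-9))  # monotone in family size
    expect_gte(p_t[4], p_raw - 1e-12)      # adjusted >= unadjusted
    expect_equal(p_t[1], p_raw, tolerance = 1e-9)  # k = 2 is the t-test
  }
})

test_that("log2 fold changes follow the worked arithmetic", {
  expect_equal(log2_fold_change(rep(8, 4), rep(4, 4)), 1)
  expect_equal(log2_fold_change(c(2, 4), c(4, 2)), 0)
  expect_true(is.na(log2_fold_change(c(0, 0), c(1, 2))))
  expect_error(log2_fold_change(numeric(0), 1), "empty")
})

test_that("the significance rule reproduces the worked triple", {
  da <- data.frame(
    species = c("TG-52:3", "PC-36:2", "PE-38:4"),
    class = c("TG", "PC", "PE"), diet_group = "D0_VO",
    log2FC = c(1.02, 0.9, 1.5), p = c(0.04, 0.001, 0.06),
    mean_sw = 1, mean_fw = 1, p_diet = NA, p_stage = NA,
    p_interaction = NA, degenerate = FALSE)
  class(da) <- c("da_result", "data.frame")
  filt <- significance_filter(da)
  expect_identical(filt$contrasts$significant, c(TRUE, FALSE, FALSE))
  expect_equal(filt$n_significant, 1L)
})

test_that("the full filter's null type-I error never exceeds the p gate alone", {
  set.seed(85)
  d <- make_design(3L)
  n_sp <- 300L
  res <- t(vapply(seq_len(n_sp), function(i) {
    x <- 2^rnorm(nrow(d), 10, 0.3)
    av <- two_way_anova(log2(x), d$diet, d$stage)
    a <- x[d$diet == "D0_FO" & d$stage == "SW"]
    b <- x[d$diet == "D0_FO" & d$stage == "FW"]
    c(p = av$p_stage, lfc = log2_fold_change(a, b))
  }, c(p = 0, lfc = 0)))
  rej_p <- mean(res[, "p"] < 0.05)
  rej_full <- mean(res[, "p"] < 0.05 & abs(res[, "lfc"]) > 1)
  expect_lte(rej_full, rej_p)
  expect_lte(rej_full, 0.05)  # FC gate only removes rejections
})

test_that("heatmap groups are deterministic and recover planted archetypes", {
  # two identical rows end up together; anti-correlated blocks split at k=2
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1),
             d = c(4.2, 3.1, 2.2, 1.0))
  hg <- heatmap_groups(m, k = 2)
  expect_equal(hg$groups[["a"]], hg$groups[["b"]])
  expect_false(hg$groups[["a"]] == hg$groups[["c"]])
  expect_equal(hg$groups[["c"]], hg$groups[["d"]])
  expect_equal(sort(unique(unname(hg$groups))), c("A", "B"))
  # three planted temporal archetypes recovered at k = 3
  set.seed(86)
  arch <- rbind(rising = seq(-1, 1, length.out = 8),
                falling = seq(1, -1, length.out = 8),
                pulse = c(-1, 2, 2, -1, -1, -1, 2, -1))
  truth_lab <- rep(rownames(arch), times = c(12, 12, 12))
  prof <- arch[truth_lab, ] * runif(36, 2, 4) +
    matrix(rnorm(36 * 8, 0, 0.15), 36, 8)
  rownames(prof) <- paste0("sp", 1:36)
  hg3 <- heatmap_groups(prof, k = 3)
  expect_gte(adjusted_rand(hg3$groups, truth_lab), 0.9)
  # single species: trivial single group
  single <- heatmap_groups(m[1, , drop = FALSE])
  expect_equal(unname(single$groups), "A")
})
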