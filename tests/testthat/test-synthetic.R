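test_that("identical seeds give bit-identical experiments", {
  g1 <- generate_experiment(small_sim_config(), seed = 31)
  g2 <- generate_experiment(small_sim_config(), seed = 31)
  expect_identical(g1$dataset$abundance, g2$dataset$abundance)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_experiment(small_sim_config(), seed = 32)
  expect_false(identical(g1$dataset$abundance, g3$dataset$abundance))
  expect_error(generate_experiment(small_sim_config()), "seed")
})

test_that("the design is balanced with every species in the truth table", {
  gen <- generate_experiment(small_sim_config(), seed = 33)
  meta <- gen$dataset$sample_meta
  expect_equal(nrow(meta), 1 * 2 * 8 * 4)  # tissue x stage x group x fish
  counts <- table(meta$diet_group, meta$stage)
  expect_true(all(counts == 4))
  expect_setequal(gen$truth$name, colnames(gen$dataset$abundance))
  expect_true(all(gen$dataset$abundance > 0))
  # day-5/6 groups sampled at day 5 in FW and day 6 in SW
  mid <- meta[meta$diet_group == "D5/6_FOVO", ]
  expect_true(all(mid$day[mid$stage == "FW"] == 5))
  expect_true(all(mid$day[mid$stage == "SW"] == 6))
})

test_that("an immediate-equilibration rate reaches the target by day 1", {
  cfg <- small_sim_config()
  cfg$k[] <- 1e6
  cfg$tank_sd <- 0
  gen <- generate_experiment(cfg, seed = 34)
  meta <- gen$dataset$sample_meta
  truth <- gen$truth
  strong <- which(abs(truth$diet_delta) > 1.5)[1:5]
  for (j in strong) {
    d1 <- gen$dataset$abundance[meta$diet_group == "D1_FOVO" &
                                  meta$stage == "FW", j]
    d0_vo <- gen$dataset$abundance[meta$diet_group == "D0_VO" &
                                     meta$stage == "FW", j]
    # day-1 switched fish already sit at the target steady state
    expect_equal(mean(log2(d1)), mean(log2(d0_vo)),
                 tolerance = 4 * 0.22 / sqrt(4))
  }
})

test_that("a zero rate leaves switched fish at their source state", {
  cfg <- small_sim_config()
  cfg$k[] <- 0
  cfg$tank_sd <- 0
  gen <- generate_experiment(cfg, seed = 35)
  meta <- gen$dataset$sample_meta
  truth <- gen$truth
  strong <- which(abs(truth$diet_delta) > 1.5)[1:5]
  for (j in strong) {
    d20 <- gen$dataset$abundance[meta$diet_group == "D20_FOVO" &
                                   meta$stage == "FW", j]
    d0_fo <- gen$dataset$abundance[meta$diet_group == "D0_FO" &
                                     meta$stage == "FW", j]
    expect_equal(mean(log2(d20)), mean(log2(d0_fo)),
                 tolerance = 4 * 0.22 / sqrt(4))
  }
})

test_that("empirical noise CV converges to the configured CV", {
  set.seed(36)
  cv <- 0.15
  for (n in c(200L, 2000L, 20000L)) {
    x <- 2^(10 + rnorm(n, 0, sqrt(log(1 + cv^2)) / log(2)))
    expect_equal(sd(x) / mean(x), cv, tolerance = 4 / sqrt(n) + 0.01)
  }
  # generated replicate cells reproduce the configured CV once cells are
  # large enough for the sd estimator's small-sample bias to vanish
  cfg <- sim_config(n_species = c(TG = 24L, PC = 16L, PE = 10L, DG = 6L,
                                  Other = 8L),
                    tissues = "gut", tank_sd = 0, fish_per_tank = 50L)
  gen <- generate_experiment(cfg, seed = 36)
  meta <- gen$dataset$sample_meta
  cell <- meta$diet_group == "D0_FO" & meta$stage == "FW"
  cvs <- apply(gen$dataset$abundance[cell, ], 2,
               function(x) sd(x) / mean(x))
  expect_lt(abs(mean(cvs) - cv), 0.01)
})

test_that("truth tables give closed-form expected fold changes", {
  cfg <- small_sim_config()
  gen <- generate_experiment(cfg, seed = 37)
  truth <- gen$truth
  # null species expect 0; planted offsets are returned exactly at D0
  tc <- truth_contrast_table(truth, "stage_within_group", tissue = "gut",
                             group = "D0_FO")
  expect_equal(tc$expected_log2FC, truth$stage_offset)
  # switched-vs-control residual at day 20 decays as exp(-20k)
  k <- attr(truth, "k")["SW", "gut"]
  tc20 <- truth_contrast_table(truth, "switched_vs_control",
                               tissue = "gut", stage = "SW", day = "20")
  expect_lt(max(abs(tc20$expected_log2FC -
                      (truth$y_FO - truth$y_VO) * exp(-20 * k))), 1e-12)
  # at a switched group the stage contrast adds the kinetic mismatch
  tc1 <- truth_contrast_table(truth, "stage_within_group", tissue = "gut",
                              group = "D1_FOVO")
  kFW <- attr(truth, "k")["FW", "gut"]; kSW <- attr(truth, "k")["SW", "gut"]
  manual <- truth$stage_offset +
    (truth$y_FO - truth$y_VO) * (exp(-kSW * 1) - exp(-kFW * 1))
  expect_equal(tc1$expected_log2FC, manual, tolerance = 1e-12)
  expect_error(truth_contrast_table(truth, "stage_within_group",
                                    tissue = "gut", group = "D9_XX"),
               "unknown diet group")
})

test_that("the remodeling rate is recoverable from group means", {
  set.seed(38)
  ks <- k_recovery_study(n_rep = 40L)
  expect_gte(ks$success_rate, 0.8)
  # and the fitted steady states bracket the truth
  f <- fit_remodeling_rate(c(0, 1, 5, 20),
                           remodeling_trajectory(c(0, 1, 5, 20), 2, 0, 0.3),
                           remodeling_trajectory(c(0, 1, 5, 20), 0, 2, 0.3))
  expect_equal(f$k, 0.3, tolerance = 1e-6)
  expect_equal(f$y_FO, 2, tolerance = 1e-6)
  expect_equal(f$y_VO, 0, tolerance = 1e-6)
})

test_that("CPCA separates diet histories on a strongly remodeled lipidome", {
  # slow-turnover muscle keeps FO- and VO-history fish apart through day 20
  cfg <- sim_config(n_species = c(TG = 24L, PC = 16L, PE = 10L, DG = 6L,
                                  Other = 8L),
                    tissues = "muscle", diet_frac = 0.8)
  gen <- generate_experiment(cfg, seed = 39)
  norm <- normalize_to_all(gen$dataset)
  bs <- preprocess_blocks(norm$dataset)
  m <- fit_cpca(bs, n_components = 2)
  meta <- norm$dataset$sample_meta
  dgmap <- setNames(diet_groups()$source, diet_groups()$group)
  history <- unname(dgmap[meta$diet_group])
  s1 <- m$global_scores[, 1]
  sil <- vapply(seq_along(s1), function(i) {
    a <- mean(abs(s1[i] - s1[history == history[i]][-i]))
    b <- mean(abs(s1[i] - s1[history != history[i]]))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})
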