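test_that("single-block CPCA degenerates to ordinary PCA", {
  set.seed(71)
  X <- scale(matrix(rnorm(20 * 8), 20, 8))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("v", 1:8)
  bs <- make_random_block_set(20, 8)
  bs$blocks <- bs$blocks[1]
  bs$blocks[[1]]$matrix <- X / sqrt(sum(X^2))
  m <- fit_cpca(bs, n_components = 3)
  pc <- prcomp(X / sqrt(sum(X^2)), center = FALSE, scale. = FALSE)
  for (a in 1:3) {
    d <- min(max(abs(m$global_scores[, a] - pc$x[, a])),
             max(abs(m$global_scores[, a] + pc$x[, a])))
    expect_lt(d, 1e-8)
  }
})

test_that("global scores reproduce the concatenated-matrix SVD (oracle)", {
  set.seed(72)
  for (rep in 1:5) {
    bs <- make_random_block_set(sample(10:40, 1),
                                sample(4:30, 5, replace = TRUE))
    m <- fit_cpca(bs, n_components = 3)
    sv <- svd(concat_blocks(bs))
    for (a in 1:3) {
      t_hat <- m$global_scores[, a] / sqrt(sum(m$global_scores[, a]^2))
      u <- sv$u[, a]
      expect_lt(min(sqrt(sum((t_hat - u)^2)), sqrt(sum((t_hat + u)^2))),
                1e-6)
      # score norm equals the singular value
      expect_equal(sqrt(sum(m$global_scores[, a]^2)), sv$d[a],
                   tolerance = 1e-6)
    }
  }
})

test_that("rank-1 noiseless blocks are fully explained by component 1", {
  set.seed(73)
  t0 <- rnorm(15)
  blocks <- lapply(1:5, function(b) {
    X <- outer(t0, rnorm(6))
    X <- scale(X, scale = FALSE)  # centered, rank 1
    list(matrix = X / sqrt(sum(X^2)), means = rep(0, 6), sds = rep(1, 6),
         weight = sqrt(sum(X^2)),
         species = paste0("b", b, "v", 1:6))
  })
  names(blocks) <- paste0("B", 1:5)
  for (b in 1:5) colnames(blocks[[b]]$matrix) <- blocks[[b]]$species
  bs <- structure(list(blocks = blocks, partition = NULL,
                       sample_ids = paste0("s", 1:15)),
                  class = "block_set")
  m <- fit_cpca(bs, n_components = 1)
  expect_equal(m$ev$global[1], 1, tolerance = 1e-10)
  expect_true(all(abs(m$ev$block[, 1] - 1) < 1e-10))
})

test_that("model invariants: orthogonality, unit weights, EV behavior, deflation", {
  bs <- make_random_block_set(18, c(5, 9, 4, 7, 6), seed = 74)
  m <- fit_cpca(bs, n_components = 4)
  S <- m$global_scores
  for (a in 1:3) for (b in (a + 1):4) {
    expect_lt(abs(sum(S[, a] * S[, b])) /
                (sqrt(sum(S[, a]^2)) * sqrt(sum(S[, b]^2))), 1e-8)
  }
  expect_equal(colSums(m$super_weights^2), rep(1, 4), tolerance = 1e-10)
  expect_true(all(diff(m$ev$global) <= 1e-10))  # global EV non-increasing
  expect_true(all(m$ev$global >= 0 & m$ev$global <= 1))
  expect_true(all(m$ev$block >= -1e-12 & m$ev$block <= 1 + 1e-12))
  # residual blocks orthogonal to every extracted super score
  for (b in seq_along(m$residual_blocks)) {
    proj <- crossprod(m$residual_blocks[[b]], S)
    expect_lt(max(abs(proj)), 1e-8)
  }
  # over all extractable components the EV sums to 1
  full <- fit_cpca(bs, n_components = 17)
  expect_equal(sum(full$ev$global), 1, tolerance = 1e-8)
})

test_that("the sign convention makes refits bit-identical", {
  bs <- make_random_block_set(16, c(6, 6, 5, 8, 4), seed = 75)
  m1 <- fit_cpca(bs, n_components = 3)
  m2 <- fit_cpca(bs, n_components = 3)
  expect_identical(m1$global_scores, m2$global_scores)
  expect_identical(m1$super_weights, m2$super_weights)
  # the largest-magnitude concatenated loading is positive per component
  for (a in 1:3) {
    pall <- unlist(lapply(m1$block_loadings, function(P) P[, a]))
    expect_gt(pall[which.max(abs(pall))], 0)
  }
})

test_that("correlation loadings measure per-variable explained variance", {
  bs <- make_random_block_set(24, c(6, 8, 5, 7, 6), seed = 76)
  m <- fit_cpca(bs, n_components = 3)
  t1 <- m$global_scores[, 1]
  t2 <- m$global_scores[, 2]
  # a variable equal to score 1 has r = (1, 0) and EV = 1
  X <- cbind(v_score = t1,
             v_span = 0.6 * t1 - 1.1 * t2,
             v_const_plus = 5 + 2 * t2)
  cl <- correlation_loadings(m, X, components = 1:2)
  expect_equal(cl$r1[1], 1, tolerance = 1e-10)
  expect_equal(cl$r2[1], 0, tolerance = 1e-10)
  expect_equal(cl$explained_variance[1:3], rep(1, 3), tolerance = 1e-10)
  # a variable orthogonal to both plotted scores has EV ~ 0
  t3 <- m$global_scores[, 3]
  cl3 <- correlation_loadings(m, cbind(v3 = t3), components = 1:2)
  expect_lt(cl3$explained_variance[1], 1e-12)
  expect_error(correlation_loadings(m, X, components = c(1, 9)),
               "out of range")
})

test_that("score plot tables join metadata at global and block level", {
  gen <- generate_experiment(small_sim_config(), seed = 9)
  norm <- normalize_to_all(gen$dataset)
  bs <- preprocess_blocks(norm$dataset)
  m <- fit_cpca(bs, n_components = 2)
  g <- score_plot_data(m, gen$dataset$sample_meta, "global")
  expect_equal(nrow(g), nrow(gen$dataset$abundance))
  expect_true(all(c("diet_group", "stage", "score_x", "score_y") %in%
                    names(g)))
  b <- score_plot_data(m, gen$dataset$sample_meta, "PC")
  expect_equal(b$score_x, m$block_scores[[which(m$block_names == "PC")]][, 1])
  expect_error(score_plot_data(m, gen$dataset$sample_meta, "XX"),
               "unknown block")
  expect_error(score_plot_data(m, gen$dataset$sample_meta, "global",
                               components = c(1, 3)), "out of range")
})
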