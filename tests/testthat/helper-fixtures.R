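# shared fixtures, all built in code

# random autoscaled + block-SS-scaled block set
make_random_block_set <- function(n, p_per_block, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_along(p_per_block), function(b) {
    X <- matrix(rnorm(n * p_per_block[b]), n, p_per_block[b])
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    list(matrix = X / sqrt(sum(X^2)), means = rep(0, ncol(X)),
         sds = rep(1, ncol(X)), weight = sqrt(sum(X^2)),
         species = paste0("b", b, "v", seq_len(p_per_block[b])))
  })
  names(blocks) <- paste0("B", seq_along(p_per_block))
  for (b in seq_along(blocks)) {
    colnames(blocks[[b]]$matrix) <- blocks[[b]]$species
  }
  structure(list(blocks = blocks, partition = NULL,
                 sample_ids = paste0("s", seq_len(n))),
            class = "block_set")
}

# tiny balanced 8x2 design with n fish per cell
make_design <- function(n_per_cell = 4L) {
  dg <- diet_groups()$group
  data.frame(
    diet = factor(rep(dg, each = 2L * n_per_cell), levels = dg),
    stage = factor(rep(rep(c("FW", "SW"), each = n_per_cell),
                       times = length(dg)))
  )
}

# small full experiment reused across integration tests
small_sim_config <- function() {
  sim_config(n_species = c(TG = 24L, PC = 16L, PE = 10L, DG = 6L,
                           Other = 8L),
             tissues = "gut")
}

# brute-force balanced two-way ANOVA decomposition from cell means
brute_force_anova_ss <- function(y, diet, stage) {
  gm <- mean(y)
  di <- tapply(y, diet, mean)
  st <- tapply(y, stage, mean)
  cm <- tapply(y, interaction(diet, stage), mean)
  n_d <- table(diet)[1]
  n_s <- table(stage)[1]
  n_c <- table(interaction(diet, stage))[1]
  ss_diet <- sum(n_d * (di - gm)^2)
  ss_stage <- sum(n_s * (st - gm)^2)
  cell_label <- interaction(diet, stage)
  fitted_cells <- cm[as.character(cell_label)]
  ss_cells <- sum(n_c * (cm - gm)^2)
  ss_int <- ss_cells - ss_diet - ss_stage
  ss_err <- sum((y - fitted_cells)^2)
  c(diet = unname(ss_diet), stage = unname(ss_stage),
    interaction = unname(ss_int), error = unname(ss_err))
}

# brute-force acyl composition enumeration over the full Cartesian product
brute_force_compositions <- function(carbons, db, m, pool_cs, pool_dbs) {
  grid <- do.call(expand.grid, rep(list(seq_along(pool_cs)), m))
  hits <- grid[rowSums(matrix(pool_cs[as.matrix(grid)], ncol = m)) == carbons &
               rowSums(matrix(pool_dbs[as.matrix(grid)], ncol = m)) == db, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  keys <- apply(hits, 1L, function(i) {
    i <- as.integer(i)
    o <- order(pool_cs[i], pool_dbs[i])
    paste(sprintf("%03d:%03d", pool_cs[i][o], pool_dbs[i][o]),
          collapse = ",")
  })
  sort(unique(keys))
}

composition_key <- function(comp) {
  paste(sprintf("%03d:%03d",
                vapply(comp, `[[`, 0L, "carbons"),
                vapply(comp, `[[`, 0L, "double_bonds")), collapse = ",")
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
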