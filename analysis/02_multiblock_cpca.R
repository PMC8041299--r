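#!/usr/bin/env Rscript
# Multiblock view of whole-lipidome remodeling: per tissue, normalize to all
# compounds, partition species into the TG/DG/PC/PE/Other blocks, equalize
# block sums of squares, fit consensus PCA, and export global scores, block
# scores, explained variance and correlation loadings with score/loading
# figures. Expects the tables written by 01_simulate.R.

suppressPackageStartupMessages(library(lipidblocks))

data_dir <- "results/data"
out <- "results/cpca"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds_all <- read_lipidome(file.path(data_dir, "abundance.tsv"),
                        file.path(data_dir, "sample_meta.tsv"))

for (tis in unique(ds_all$sample_meta$tissue)) {
  ds <- subset_tissue(ds_all, tis)
  norm <- normalize_to_all(ds)
  bs <- preprocess_blocks(norm$dataset)
  model <- fit_cpca(bs, n_components = 2)

  cat("\n== ", tis, " ==\n", sep = "")
  cat("normalization reference: ", norm$reference,
      "; factors in [", sprintf("%.3f", min(norm$factors)), ", ",
      sprintf("%.3f", max(norm$factors)), "]\n", sep = "")
  cat("global EV: ",
      paste(sprintf("%.1f%%", 100 * model$ev$global), collapse = ", "),
      "\n", sep = "")
  cat("block EV on component 1: ",
      paste(model$block_names,
            sprintf("%.1f%%", 100 * model$ev$block[, 1]),
            sep = " ", collapse = ", "), "\n", sep = "")

  sc <- data.frame(sample_id = model$sample_ids, model$global_scores)
  names(sc)[-1] <- c("PC1", "PC2")
  write.table(sc, file.path(out, paste0(tis, "_global_scores.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(component = 1:2, global = model$ev$global,
                   t(model$ev$block))
  write.table(ev, file.path(out, paste0(tis, "_explained_variance.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- correlation_loadings(model, norm$dataset$abundance)
  write.table(cl, file.path(out, paste0(tis, "_correlation_loadings.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  p1 <- plot_scores(model, ds$sample_meta) +
    ggplot2::ggtitle(paste("Global score plot:", tis))
  ggplot2::ggsave(file.path(out, paste0(tis, "_global_scores.pdf")), p1,
                  width = 7, height = 5)
  p2 <- plot_correlation_loadings(cl) +
    ggplot2::ggtitle(paste("Correlation loadings:", tis))
  ggplot2::ggsave(file.path(out, paste0(tis, "_correlation_loadings.pdf")),
                  p2, width = 6.5, height = 5.5)
}
cat("\nScore, EV and loading tables written under ", out, "\n", sep = "")
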