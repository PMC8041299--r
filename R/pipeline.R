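#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Unknown fields are
#' rejected so config-file typos cannot silently fall back to defaults.
#'
#' @param abundance_path,meta_path Input tables (ignored when
#'   \code{simulate} is TRUE).
#' @param simulate Generate the input with [generate_experiment()] instead
#'   of reading files (default TRUE).
#' @param sim A \code{sim_config} for the generator.
#' @param tissues Tissues to analyze (NULL = all present).
#' @param normalization \code{"median_ratio"} or \code{"total_sum"}.
#' @param reference Reference sample for normalization (default
#'   \code{"auto"}).
#' @param n_components CPCA components (default 2).
#' @param cpca_tol,cpca_max_iter CPCA convergence controls.
#' @param p_type \code{"tukey"} or \code{"anova"} (see
#'   [differential_abundance()]).
#' @param lfc_threshold,alpha Significance filter gates (defaults 1, 0.05).
#' @param cluster_k Heatmap cluster-group count (default 4).
#' @param out_dir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @param make_plots Write figure files (default FALSE).
#' @return A validated \code{pipeline_config}.
#' @export
pipeline_config <- function(abundance_path = NULL, meta_path = NULL,
                            simulate = TRUE, sim = sim_config(),
                            tissues = NULL,
                            normalization = "median_ratio",
                            reference = "auto",
                            n_components = 2L, cpca_tol = 1e-10,
                            cpca_max_iter = 10000L,
                            p_type = "tukey", lfc_threshold = 1,
                            alpha = 0.05, cluster_k = 4L,
                            out_dir = "results/pipeline", seed = 1L,
                            make_plots = FALSE) {
  cfg <- list(abundance_path = abundance_path, meta_path = meta_path,
              simulate = simulate, sim = sim, tissues = tissues,
              normalization = normalization, reference = reference,
              n_components = n_components, cpca_tol = cpca_tol,
              cpca_max_iter = cpca_max_iter, p_type = p_type,
              lfc_threshold = lfc_threshold, alpha = alpha,
              cluster_k = cluster_k, out_dir = out_dir, seed = seed,
              make_plots = make_plots)
  if (cfg$lfc_threshold <= 0 || cfg$alpha <= 0) {
    stop("filter thresholds must be positive", call. = FALSE)
  }
  if (!cfg$normalization %in% c("median_ratio", "total_sum")) {
    stop("unknown normalization '", cfg$normalization, "'", call. = FALSE)
  }
  if (!cfg$p_type %in% c("tukey", "anova")) {
    stop("unknown p_type '", cfg$p_type, "'", call. = FALSE)
  }
  if (!cfg$simulate) {
    for (p in c(cfg$abundance_path, cfg$meta_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file not found: ", if (is.null(p)) "(missing path)"
             else p, call. = FALSE)
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. The nested \code{sim} entry is passed to [sim_config()].
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$sim)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(raw$sim), sim_known)
    if (length(sim_unknown)) {
      stop("unknown sim config keys: ", paste(sim_unknown, collapse = ", "),
           call. = FALSE)
    }
    raw$sim <- do.call(sim_config, raw$sim)
  }
  do.call(pipeline_config, raw)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full lipidome analysis pipeline
#'
#' Simulate (or read) the experiment, then per tissue: normalize, build the
#' five class blocks, fit CPCA, compute correlation loadings, run the
#' per-species differential analysis, apply the significance filter and
#' assign heatmap cluster groups. All result tables are written as
#' tab-delimited text under \code{out_dir}; a JSON manifest records the
#' configuration, seed, stage log and an md5 checksum per output file, so
#' two runs with the same seed can be compared byte for byte.
#'
#' @param config A \code{pipeline_config}.
#' @return Invisibly, the manifest (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  files <- character(0)
  warnings_seen <- character(0)

  if (config$simulate) {
    note("stage simulate: seed ", config$seed)
    gen <- generate_experiment(config$sim, seed = config$seed)
    ds_all <- gen$dataset
    files <- c(files, write_lipidome(
      ds_all,
      file.path(config$out_dir, "abundance.tsv"),
      file.path(config$out_dir, "sample_meta.tsv")))
    files <- c(files, .write_tsv(gen$truth,
                                 file.path(config$out_dir, "truth.tsv")))
  } else {
    note("stage ingest: ", config$abundance_path)
    ds_all <- read_lipidome(config$abundance_path, config$meta_path)
  }
  note("dataset: ", nrow(ds_all$abundance), " samples x ",
       ncol(ds_all$abundance), " species")

  tissues <- if (is.null(config$tissues)) {
    unique(ds_all$sample_meta$tissue)
  } else {
    config$tissues
  }
  summary_rows <- list()

  for (tis in tissues) {
    ds <- subset_tissue(ds_all, tis)
    norm <- normalize_to_all(ds, reference = config$reference,
                             method = config$normalization)
    note("stage preprocess [", tis, "]: reference ", norm$reference)
    files <- c(files, .write_tsv(
      data.frame(sample_id = names(norm$factors),
                 factor = unname(norm$factors)),
      file.path(config$out_dir, paste0(tis, "_norm_factors.tsv"))))

    bs <- preprocess_blocks(norm$dataset)
    model <- withCallingHandlers(
      fit_cpca(bs, n_components = config$n_components,
               tol = config$cpca_tol, max_iter = config$cpca_max_iter),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0("[", tis, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    note("stage cpca [", tis, "]: global EV ",
         paste(sprintf("%.1f%%", 100 * model$ev$global), collapse = ", "))

    sc <- data.frame(sample_id = model$sample_ids, model$global_scores)
    names(sc)[-1] <- paste0("PC", seq_len(config$n_components))
    files <- c(files, .write_tsv(
      sc, file.path(config$out_dir, paste0(tis, "_global_scores.tsv"))))
    for (b in seq_along(model$block_names)) {
      bsc <- data.frame(sample_id = model$sample_ids,
                        model$block_scores[[b]])
      names(bsc)[-1] <- paste0("PC", seq_len(config$n_components))
      files <- c(files, .write_tsv(
        bsc, file.path(config$out_dir,
                       paste0(tis, "_block_scores_",
                              model$block_names[b], ".tsv"))))
    }
    ev <- data.frame(component = seq_len(config$n_components),
                     global = model$ev$global,
                     t(model$ev$block))
    files <- c(files, .write_tsv(
      ev, file.path(config$out_dir, paste0(tis, "_explained_variance.tsv"))))

    cl <- correlation_loadings(model, norm$dataset$abundance,
                               components = seq_len(min(2L,
                                                        config$n_components)))
    files <- c(files, .write_tsv(
      cl, file.path(config$out_dir,
                    paste0(tis, "_correlation_loadings.tsv"))))

    da <- differential_abundance(norm$dataset, p_type = config$p_type)
    filt <- significance_filter(da, config$lfc_threshold, config$alpha)
    note("stage da [", tis, "]: ", filt$n_significant,
         " significant species")
    flagged <- filt$species$species[filt$species$significant]
    groups <- if (length(flagged) >= 2L) {
      hm <- heatmap_groups(cell_mean_matrix(norm$dataset, flagged),
                           k = config$cluster_k)
      hm$groups
    } else {
      stats::setNames(rep("A", length(flagged)), flagged)
    }
    res <- filt$contrasts
    res$cluster_group <- groups[res$species]
    files <- c(files, .write_tsv(
      res, file.path(config$out_dir, paste0(tis, "_da_results.tsv"))))

    if (config$make_plots) {
      files <- c(files, .pipeline_plots(config, tis, model,
                                        norm$dataset$sample_meta, cl))
    }
    summary_rows[[tis]] <- data.frame(
      tissue = tis, n_species = ncol(ds$abundance),
      n_significant = filt$n_significant,
      ev1 = model$ev$global[1L],
      ev2 = if (config$n_components >= 2L) model$ev$global[2L] else NA_real_)
  }

  summary <- do.call(rbind, summary_rows)
  files <- c(files, .write_tsv(summary,
                               file.path(config$out_dir, "summary.tsv")))

  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_md5 = .md5_string(as.character(cfg_json)),
    seed = config$seed,
    log = log_lines,
    warnings = warnings_seen,
    checksums = {
      fs <- sort(unique(files))
      stats::setNames(as.list(unname(tools::md5sum(fs))), basename(fs))
    }
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

.pipeline_plots <- function(config, tissue, model, meta, cl) {
  out <- character(0)
  p1 <- plot_scores(model, meta, level = "global") +
    ggplot2::ggtitle(paste("Global scores:", tissue))
  f1 <- file.path(config$out_dir, paste0(tissue, "_global_scores.pdf"))
  ggplot2::ggsave(f1, p1, width = 6, height = 5)
  p2 <- plot_correlation_loadings(cl) +
    ggplot2::ggtitle(paste("Correlation loadings:", tissue))
  f2 <- file.path(config$out_dir,
                  paste0(tissue, "_correlation_loadings.pdf"))
  ggplot2::ggsave(f2, p2, width = 6, height = 5)
  c(out, f1, f2)
}
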