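#' Balanced two-way ANOVA for one lipid species
#'
#' Classical fixed-effects decomposition with interaction for the 8 diet
#' groups x 2 life stages design, fitted on log-transformed normalized
#' abundance (variance stabilization for multiplicative error). For balanced
#' data the sums of squares partition exactly:
#' SS_total = SS_diet + SS_stage + SS_interaction + SS_error.
#'
#' @param values Numeric vector of log abundances, one per fish.
#' @param diet Factor (or coercible) of diet-group labels.
#' @param stage Factor of life-stage labels.
#' @return A list with p-values for diet, stage and interaction, the error
#'   mean square \code{mse}, \code{df_error}, the ANOVA table, and
#'   \code{degenerate} (TRUE when the within-cell variance is essentially
#'   zero, in which case the p-values are NA).
#' @export
two_way_anova <- function(values, diet, stage) {
  diet <- droplevels(as.factor(diet))
  stage <- droplevels(as.factor(stage))
  stopifnot(length(values) == length(diet), length(values) == length(stage))
  cell <- table(diet, stage)
  if (any(cell == 0L)) {
    bad <- which(cell == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: diet '", levels(diet)[bad[1L]], "' x stage '",
         levels(stage)[bad[2L]], "'", call. = FALSE)
  }
  if (length(unique(as.vector(cell))) != 1L) {
    stop("unbalanced design: unequal cell counts", call. = FALSE)
  }
  fit <- stats::lm(values ~ diet * stage)
  tab <- suppressWarnings(stats::anova(fit))
  ss_err <- tab["Residuals", "Sum Sq"]
  # an essentially perfect fit (constant data or zero within-cell variance)
  # has no error stratum to test against
  degenerate <- ss_err <= sum(values^2) * 1e-12
  p <- if (degenerate) rep(NA_real_, 3L) else tab[c("diet", "stage",
                                                    "diet:stage"), "Pr(>F)"]
  list(p_diet = p[1L], p_stage = p[2L], p_interaction = p[3L],
       mse = tab["Residuals", "Mean Sq"],
       df_error = tab["Residuals", "Df"],
       table = tab, degenerate = degenerate)
}

#' Tukey HSD adjusted p-value for a pairwise cell contrast
#'
#' Studentized-range p-value for the difference of two cell means in a
#' balanced design, with the family size k equal to the number of cell means
#' compared (default all 16 diet x stage cells).
#'
#' @param mean_a,mean_b The two cell means (on the ANOVA's log scale).
#' @param mse Error mean square from the ANOVA.
#' @param df_error Error degrees of freedom.
#' @param n_per_cell Replicates per cell (>= 2).
#' @param k_family Number of means in the Tukey family (default 16).
#' @return Adjusted p-value in [0, 1].
#' @export
tukey_hsd_p <- function(mean_a, mean_b, mse, df_error, n_per_cell,
                        k_family = 16L) {
  if (n_per_cell < 2L) stop("need n >= 2 per cell", call. = FALSE)
  if (mse <= 0 || !is.finite(mse)) return(NA_real_)
  q <- abs(mean_a - mean_b) / sqrt(mse / n_per_cell)
  stats::ptukey(q, nmeans = k_family, df = df_error, lower.tail = FALSE)
}

#' Log2 fold change between two groups
#'
#' log2 of the ratio of group means of normalized (untransformed) abundance,
#' the scale on which fold changes are conventionally reported.
#'
#' @param group_a,group_b Numeric vectors of normalized abundances.
#' @return log2(mean(group_a) / mean(group_b)); NA with a warning-free
#'   undefined flag when either mean is non-positive.
#' @export
log2_fold_change <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("empty group", call. = FALSE)
  }
  ma <- mean(group_a)
  mb <- mean(group_b)
  if (ma <= 0 || mb <= 0) return(NA_real_)
  log2(ma / mb)
}

#' Per-species differential abundance across diet groups and life stages
#'
#' For every species in one tissue: two-way ANOVA (on log2 normalized
#' abundance) over the 8 diet groups x 2 stages, Tukey-HSD adjusted p-values
#' for the stage contrast (FW vs SW) within each diet group, and log2 fold
#' changes (SW over FW) of the cell means on the normalized scale.
#'
#' @param dataset A normalized \code{lipidome_dataset} restricted to one
#'   tissue.
#' @param p_type Which p-value enters the significance rule:
#'   \code{"tukey"} (default; the adjusted pairwise p of each within-diet
#'   stage contrast) or \code{"anova"} (the stage main-effect p, applied to
#'   every contrast).
#' @param k_family Tukey family size (default 16, all diet x stage cells).
#' @return A \code{da_result} data.frame, one row per species x contrast:
#'   species, class, diet_group, log2FC (SW/FW), p (per \code{p_type}),
#'   p_diet/p_stage/p_interaction from the ANOVA, and the cell means.
#' @export
differential_abundance <- function(dataset, p_type = c("tukey", "anova"),
                                   k_family = 16L) {
  stopifnot(inherits(dataset, "lipidome_dataset"))
  p_type <- match.arg(p_type)
  meta <- dataset$sample_meta
  if (length(unique(meta$tissue)) != 1L) {
    stop("differential_abundance expects a single tissue; use subset_tissue()",
         call. = FALSE)
  }
  diet <- factor(meta$diet_group, levels = unique(meta$diet_group))
  stage <- factor(meta$stage)
  if (nlevels(stage) != 2L) stop("need exactly 2 life stages", call. = FALSE)
  sw <- levels(stage)[match("SW", levels(stage), nomatch = 2L)]
  fw <- setdiff(levels(stage), sw)[1L]
  n_cell <- nrow(meta) / (nlevels(diet) * 2L)

  rows <- lapply(seq_len(ncol(dataset$abundance)), function(j) {
    x <- dataset$abundance[, j]
    if (any(x <= 0)) {
      # zeros carry no log signal; nudge to half the smallest positive value
      x <- pmax(x, min(x[x > 0]) / 2)
    }
    av <- two_way_anova(log2(x), diet, stage)
    per_group <- lapply(levels(diet), function(g) {
      a <- dataset$abundance[diet == g & stage == sw, j]
      b <- dataset$abundance[diet == g & stage == fw, j]
      lfc <- log2_fold_change(a, b)
      p_pair <- if (av$degenerate) NA_real_ else if (p_type == "tukey") {
        tukey_hsd_p(mean(log2(pmax(a, .Machine$double.xmin))),
                    mean(log2(pmax(b, .Machine$double.xmin))),
                    av$mse, av$df_error, n_cell, k_family)
      } else {
        av$p_stage
      }
      data.frame(diet_group = g, log2FC = lfc, p = p_pair,
                 mean_sw = mean(a), mean_fw = mean(b),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_group)
    out$species <- dataset$species$name[j]
    out$class <- dataset$species$class[j]
    out$p_diet <- av$p_diet
    out$p_stage <- av$p_stage
    out$p_interaction <- av$p_interaction
    out$degenerate <- av$degenerate
    out
  })
  out <- do.call(rbind, rows)
  out <- out[, c("species", "class", "diet_group", "log2FC", "p",
                 "mean_sw", "mean_fw", "p_diet", "p_stage", "p_interaction",
                 "degenerate")]
  attr(out, "tissue") <- unique(meta$tissue)
  attr(out, "p_type") <- p_type
  class(out) <- c("da_result", "data.frame")
  out
}

#' Apply the significance filter
#'
#' A species is significant when, on at least one within-diet stage
#' contrast, |log2FC| > lfc_threshold and p < alpha (defaults |log2FC| > 1,
#' p < 0.05).
#'
#' @param da A \code{da_result}.
#' @param lfc_threshold Fold-change gate (default 1 log2 unit).
#' @param alpha p-value gate (default 0.05).
#' @return List with \code{contrasts} (the input plus a \code{significant}
#'   flag per contrast), \code{species} (per-species any-contrast flag) and
#'   \code{n_significant}.
#' @export
significance_filter <- function(da, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(da, "da_result") || is.data.frame(da))
  sig <- !is.na(da$log2FC) & !is.na(da$p) &
    abs(da$log2FC) > lfc_threshold & da$p < alpha
  da$significant <- sig
  per_species <- tapply(sig, da$species, any)
  species <- data.frame(species = names(per_species),
                        significant = as.vector(per_species),
                        stringsAsFactors = FALSE)
  list(contrasts = da, species = species,
       n_significant = sum(species$significant))
}

#' Heatmap cluster groups for flagged species
#'
#' Row-scales each species' cell-mean profile (mean 0, sd 1 across the
#' diet x stage cells), clusters species by average-linkage hierarchical
#' clustering on Euclidean distance, cuts the tree into \code{k} groups and
#' labels them A, B, C, ... in dendrogram order (deterministic).
#'
#' @param cell_means Species x cells matrix of group means (normalized
#'   scale).
#' @param k Number of groups to cut (default 4).
#' @return List with \code{groups} (named character vector of labels),
#'   \code{scaled} (the row-scaled matrix) and \code{hclust} (the tree, NULL
#'   for fewer than 2 species).
#' @export
heatmap_groups <- function(cell_means, k = 4L) {
  stopifnot(is.matrix(cell_means))
  if (nrow(cell_means) < 2L) {
    return(list(groups = setNames(rep("A", nrow(cell_means)),
                                  rownames(cell_means)),
                scaled = cell_means, hclust = NULL))
  }
  mu <- rowMeans(cell_means)
  sd <- apply(cell_means, 1L, stats::sd)
  sd[sd == 0] <- 1  # flat profiles scale to all-zero rows
  scaled <- sweep(sweep(cell_means, 1L, mu), 1L, sd, "/")
  hc <- stats::hclust(stats::dist(scaled), method = "average")
  k_eff <- min(k, nrow(scaled))
  raw <- stats::cutree(hc, k = k_eff)
  # relabel in dendrogram (leaf-order) position so labels are reproducible
  first_seen <- unique(raw[hc$order])
  labels <- setNames(LETTERS[seq_along(first_seen)], first_seen)
  groups <- setNames(unname(labels[as.character(raw)]), names(raw))
  list(groups = groups, scaled = scaled, hclust = hc)
}

#' Cell means of normalized abundance for flagged species
#'
#' Convenience builder for [heatmap_groups()]: per species, the mean
#' normalized abundance in each diet-group x stage cell, columns ordered by
#' stage then diet group.
#'
#' @param dataset A normalized single-tissue \code{lipidome_dataset}.
#' @param species Character vector of species to include.
#' @return Species x cells matrix.
#' @export
cell_mean_matrix <- function(dataset, species = dataset$species$name) {
  stopifnot(inherits(dataset, "lipidome_dataset"))
  meta <- dataset$sample_meta
  cellf <- interaction(factor(meta$stage),
                       factor(meta$diet_group, levels = unique(meta$diet_group)),
                       sep = ":", lex.order = TRUE)
  j <- match(species, dataset$species$name)
  if (anyNA(j)) {
    stop("unknown species: ", paste(species[is.na(j)], collapse = ", "),
         call. = FALSE)
  }
  m <- t(apply(dataset$abundance[, j, drop = FALSE], 2L, function(x)
    tapply(x, cellf, mean)))
  rownames(m) <- species
  m
}
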