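#' Fit consensus principal component analysis
#'
#' Extracts components one at a time by the iterative super-score (NIPALS
#' consensus) algorithm. Per component: the super score t is initialized to
#' the column of the concatenated matrix with maximal variance; then until
#' convergence, each block's loading p_b = X_b't (normalized to unit length)
#' gives a block score t_b = X_b p_b, the block scores are collected into
#' T = [t_1 ... t_B], the super weight w = T't / t't is normalized to unit
#' length, and the new super score is t = T w. With unit-norm block loadings
#' this iteration is a power iteration on the concatenated matrix, so the
#' super scores coincide (up to sign) with the PCA scores of the
#' column-concatenated block-scaled matrix. All blocks are then deflated by
#' the super score.
#'
#' Signs are fixed deterministically: each component is flipped, if needed,
#' so that the concatenated block loading of largest absolute value is
#' positive.
#'
#' @param block_set A \code{block_set} from [preprocess_blocks()].
#' @param n_components Number of components to extract.
#' @param tol Convergence tolerance on the relative change of the super
#'   score (default 1e-10).
#' @param max_iter Iteration cap per component (default 10000; the iteration
#'   is cheap and near-degenerate eigenvalue pairs converge slowly).
#' @return A \code{cpca_model} with \code{global_scores} (samples x
#'   components), \code{super_weights} (blocks x components, unit-norm
#'   columns), \code{block_scores} and \code{block_loadings} (lists over
#'   blocks), \code{ev} (per-component explained-variance fractions, global
#'   and per block), and \code{convergence} (iterations, final change,
#'   converged flag; non-convergence is recorded as a warning in the model,
#'   not an error).
#' @export
fit_cpca <- function(block_set, n_components = 2L, tol = 1e-10,
                     max_iter = 10000L) {
  stopifnot(inherits(block_set, "block_set"))
  Xb <- lapply(block_set$blocks, `[[`, "matrix")
  B <- length(Xb)
  n <- nrow(Xb[[1L]])
  if (!all(vapply(Xb, nrow, 0L) == n)) {
    stop("blocks disagree on the sample dimension", call. = FALSE)
  }
  p_tot <- sum(vapply(Xb, ncol, 0L))
  if (n_components > min(n - 1L, p_tot)) {
    stop("n_components exceeds min(samples - 1, total variables)",
         call. = FALSE)
  }
  ss0 <- vapply(Xb, function(X) sum(X^2), 0)
  total_ss <- sum(ss0)

  scores <- matrix(0, n, n_components,
                   dimnames = list(block_set$sample_ids, NULL))
  W <- matrix(0, B, n_components, dimnames = list(names(Xb), NULL))
  Tb_all <- lapply(Xb, function(X) matrix(0, n, n_components))
  Pb_all <- lapply(Xb, function(X)
    matrix(0, ncol(X), n_components, dimnames = list(colnames(X), NULL)))
  ev_global <- numeric(n_components)
  ev_block <- matrix(0, B, n_components, dimnames = list(names(Xb), NULL))
  conv <- data.frame(component = seq_len(n_components), iterations = 0L,
                     final_change = NA_real_, converged = FALSE)

  for (a in seq_len(n_components)) {
    Xc <- do.call(cbind, Xb)
    t <- Xc[, which.max(apply(Xc, 2L, stats::var))]
    delta <- Inf
    it <- 0L
    Tmat <- matrix(0, n, B)
    w <- numeric(B)
    while (it < max_iter) {
      it <- it + 1L
      for (b in seq_len(B)) {
        p <- crossprod(Xb[[b]], t)
        np <- sqrt(sum(p^2))
        Tmat[, b] <- if (np > 0) drop(Xb[[b]] %*% (p / np)) else 0
      }
      w <- drop(crossprod(Tmat, t)) / sum(t^2)
      w <- w / sqrt(sum(w^2))
      t_new <- drop(Tmat %*% w)
      delta <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
      t <- t_new
      if (delta < tol) break
    }
    conv$iterations[a] <- it
    conv$final_change[a] <- delta
    conv$converged[a] <- delta < tol
    if (!conv$converged[a]) {
      warning("CPCA component ", a, " did not converge in ", max_iter,
              " iterations (last change ", signif(delta, 3), ")",
              call. = FALSE)
    }
    # deflation loadings and sign convention
    tt <- sum(t^2)
    pb <- lapply(Xb, function(X) drop(crossprod(X, t)) / tt)
    pall <- unlist(pb, use.names = FALSE)
    if (pall[which.max(abs(pall))] < 0) {
      t <- -t
      pb <- lapply(pb, `-`)
      w <- -w
      Tmat <- -Tmat
    }
    scores[, a] <- t
    W[, a] <- w
    for (b in seq_len(B)) {
      Tb_all[[b]][, a] <- Tmat[, b]
      Pb_all[[b]][, a] <- pb[[b]]
      removed <- tt * sum(pb[[b]]^2)
      ev_block[b, a] <- removed / ss0[b]
      Xb[[b]] <- Xb[[b]] - tcrossprod(t, pb[[b]])
    }
    ev_global[a] <- sum(tt * vapply(pb, function(p) sum(p^2), 0)) / total_ss
  }

  structure(
    list(global_scores = scores, super_weights = W,
         block_scores = Tb_all, block_loadings = Pb_all,
         ev = list(global = ev_global, block = ev_block),
         convergence = conv, residual_blocks = Xb,
         block_names = names(block_set$blocks),
         sample_ids = block_set$sample_ids,
         n_components = n_components, tol = tol, max_iter = max_iter),
    class = "cpca_model"
  )
}

#' @export
print.cpca_model <- function(x, ...) {
  cat("<cpca_model> ", x$n_components, " components, ",
      length(x$block_names), " blocks (",
      paste(x$block_names, collapse = ", "), ")\n", sep = "")
  cat("  global EV: ",
      paste(sprintf("%.1f%%", 100 * x$ev$global), collapse = ", "), "\n",
      sep = "")
  if (!all(x$convergence$converged)) {
    cat("  warning: component(s) ",
        paste(x$convergence$component[!x$convergence$converged],
              collapse = ", "),
        " not converged\n", sep = "")
  }
  invisible(x)
}

#' Correlation loadings against global components
#'
#' Pearson correlation of each original variable (on the normalized,
#' pre-centering scale) with the requested global score vectors. The sum of
#' squared correlations over the plotted components is the fraction of the
#' variable's variance those components explain; on a correlation-loading
#' plot, a variable explained 100% lies on the unit circle and one explained
#' 50% on the circle of radius sqrt(0.5).
#'
#' @param model A \code{cpca_model}.
#' @param normalized Samples x species matrix on the normalized scale (same
#'   samples, same order, as the model was fitted on).
#' @param components Integer vector of component indices (default 1:2).
#' @return A data.frame with one row per variable: its block, one
#'   correlation column per component (\code{r1}, \code{r2}, ...), and
#'   \code{explained_variance} = sum of the squared correlations.
#' @export
correlation_loadings <- function(model, normalized, components = 1:2) {
  stopifnot(inherits(model, "cpca_model"))
  if (any(components < 1L) || any(components > model$n_components)) {
    stop("component index out of range (model has ", model$n_components,
         " components)", call. = FALSE)
  }
  if (nrow(normalized) != nrow(model$global_scores)) {
    stop("sample dimension mismatch with fitted model", call. = FALSE)
  }
  rmat <- stats::cor(normalized, model$global_scores[, components,
                                                     drop = FALSE])
  colnames(rmat) <- paste0("r", components)
  species_block <- rep(model$block_names,
                       vapply(model$block_loadings, nrow, 0L))
  names(species_block) <- unlist(lapply(model$block_loadings, rownames),
                                 use.names = FALSE)
  out <- data.frame(species = rownames(rmat),
                    block = unname(species_block[rownames(rmat)]),
                    rmat,
                    explained_variance = rowSums(rmat^2),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Score table for plotting
#'
#' @param model A \code{cpca_model}.
#' @param sample_meta Sample metadata (rows matching the fitted samples).
#' @param level \code{"global"} or a block label.
#' @param components A pair of component indices (default c(1, 2)).
#' @return A data.frame with sample id, metadata and the two score columns.
#' @export
score_plot_data <- function(model, sample_meta, level = "global",
                            components = c(1L, 2L)) {
  stopifnot(inherits(model, "cpca_model"), length(components) == 2L)
  if (any(components > model$n_components)) {
    stop("component index out of range (model has ", model$n_components,
         " components)", call. = FALSE)
  }
  if (identical(level, "global")) {
    sc <- model$global_scores
  } else {
    b <- match(level, model$block_names)
    if (is.na(b)) stop("unknown block '", level, "'", call. = FALSE)
    sc <- model$block_scores[[b]]
  }
  out <- data.frame(sample_id = model$sample_ids,
                    sample_meta[match(model$sample_ids,
                                      sample_meta$sample_id), , drop = FALSE
                                ][, setdiff(names(sample_meta), "sample_id"),
                                  drop = FALSE],
                    score_x = sc[, components[1L]],
                    score_y = sc[, components[2L]],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "components") <- components
  attr(out, "level") <- level
  out
}
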