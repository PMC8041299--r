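#' Refit the remodeling rate constant from group-mean trajectories
#'
#' Joint nonlinear least-squares fit of the exponential remodeling model to
#' the two switch arms of one (stage, tissue) series: the FOVO arm relaxes
#' from the fish-oil steady state toward the vegetable-oil one and the VOFO
#' arm does the reverse, sharing a single rate constant. Three parameters
#' (y_FO, y_VO, k) are fitted to the 2 x length(times) group means.
#'
#' @param times Sampling days (same for both arms).
#' @param mean_fovo,mean_vofo Group-mean log2 abundances per day for the
#'   FOVO and VOFO arms.
#' @param k_start Starting value for the rate constant (default 0.2/day).
#' @return List with \code{k}, \code{y_FO}, \code{y_VO} and the
#'   \code{nls} fit object; NULL on optimizer failure.
#' @export
fit_remodeling_rate <- function(times, mean_fovo, mean_vofo, k_start = 0.2) {
  stopifnot(length(times) == length(mean_fovo),
            length(times) == length(mean_vofo))
  df <- data.frame(
    y = c(mean_fovo, mean_vofo),
    t = rep(times, 2L),
    from_fo = rep(c(1, 0), each = length(times))
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ifelse(from_fo == 1,
                 yVO + (yFO - yVO) * exp(-k * t),
                 yFO + (yVO - yFO) * exp(-k * t)),
      data = df,
      start = list(yFO = mean_fovo[1L], yVO = mean_vofo[1L], k = k_start),
      lower = c(-Inf, -Inf, 1e-6), upper = c(Inf, Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  list(k = unname(co["k"]), y_FO = unname(co["yFO"]),
       y_VO = unname(co["yVO"]), fit = fit)
}

#' Rate-constant recovery study
#'
#' Simulates replicate diet-switch series under the generator's model
#' (exponential remodeling on the log2 scale, multiplicative noise) and
#' refits k with [fit_remodeling_rate()]. Per replicate: both switch arms,
#' group means of n fish per cell at each sampling day.
#'
#' @param n_rep Number of replicates.
#' @param k_true Planted rate constant (1/day).
#' @param y_fo,y_vo Planted steady-state log2 abundances.
#' @param cv Multiplicative noise CV.
#' @param n_per_cell Fish per cell.
#' @param times Sampling days.
#' @param rel_tol Relative error counted as a success (default 0.25).
#' @return List with \code{success_rate}, the vector of \code{k_hat}, and
#'   the settings.
#' @export
k_recovery_study <- function(n_rep = 200L, k_true = 0.3, y_fo = 2,
                             y_vo = 0, cv = 0.15, n_per_cell = 4L,
                             times = c(0, 1, 5, 20), rel_tol = 0.25) {
  sdn <- .sdlog2(cv)
  k_hat <- vapply(seq_len(n_rep), function(r) {
    m_fovo <- vapply(times, function(t)
      mean(remodeling_trajectory(t, y_fo, y_vo, k_true) +
             stats::rnorm(n_per_cell, 0, sdn)), 0)
    m_vofo <- vapply(times, function(t)
      mean(remodeling_trajectory(t, y_vo, y_fo, k_true) +
             stats::rnorm(n_per_cell, 0, sdn)), 0)
    f <- fit_remodeling_rate(times, m_fovo, m_vofo)
    if (is.null(f)) NA_real_ else f$k
  }, 0)
  ok <- !is.na(k_hat) & abs(k_hat - k_true) / k_true <= rel_tol
  list(success_rate = mean(ok), k_hat = k_hat, k_true = k_true,
       rel_tol = rel_tol, n_rep = n_rep)
}

#' Stage log2 fold-change recovery study
#'
#' Simulates replicate control-group comparisons with a planted life-stage
#' offset and recovers it with the differential module's estimator
#' ([log2_fold_change()] on normalized-scale cell means). Both unswitched
#' control groups (steady state on FO and on VO) carry the same offset; the
#' per-replicate estimate is the mean of the two within-diet SW-vs-FW
#' log2 fold changes.
#'
#' @param n_rep Number of replicates.
#' @param offset Planted stage offset, log2 units.
#' @param y_fo,y_vo Steady-state log2 baselines of the two control diets.
#' @param cv Multiplicative noise CV.
#' @param n_per_cell Fish per cell.
#' @param abs_tol Absolute log2 error counted as a success (default 0.3).
#' @return List with \code{success_rate}, the estimates, and the settings.
#' @export
lfc_recovery_study <- function(n_rep = 200L, offset = 1.5, y_fo = 2,
                               y_vo = 0, cv = 0.15, n_per_cell = 4L,
                               abs_tol = 0.3) {
  sdn <- .sdlog2(cv)
  draw_cell <- function(mu) 2^(mu + stats::rnorm(n_per_cell, 0, sdn))
  est <- vapply(seq_len(n_rep), function(r) {
    l_fo <- log2_fold_change(draw_cell(y_fo + offset), draw_cell(y_fo))
    l_vo <- log2_fold_change(draw_cell(y_vo + offset), draw_cell(y_vo))
    (l_fo + l_vo) / 2
  }, 0)
  ok <- abs(est - offset) <= abs_tol
  list(success_rate = mean(ok), estimates = est, offset = offset,
       abs_tol = abs_tol, n_rep = n_rep)
}

#' Monte-Carlo type-I error of the stage test
#'
#' Simulates species with no diet, stage, tank or interaction effects
#' (pure log-normal noise) under the balanced 8 x 2 design and records how
#' often the two-way ANOVA stage p-value falls below alpha.
#'
#' @param n_species Number of null species.
#' @param n_per_cell Fish per cell.
#' @param cv Multiplicative noise CV.
#' @param alpha Nominal level (default 0.05).
#' @return List with \code{rejection_rate}, the exact binomial 95% interval
#'   around alpha for this simulation size, and \code{within_interval}.
#' @export
type1_error_study <- function(n_species = 2000L, n_per_cell = 4L,
                              cv = 0.15, alpha = 0.05) {
  sdn <- .sdlog2(cv)
  dg <- diet_groups()$group
  diet <- factor(rep(dg, each = 2L * n_per_cell), levels = dg)
  stage <- factor(rep(rep(c("FW", "SW"), each = n_per_cell),
                      times = length(dg)))
  n_obs <- length(diet)
  p <- vapply(seq_len(n_species), function(i) {
    two_way_anova(stats::rnorm(n_obs, 0, sdn), diet, stage)$p_stage
  }, 0)
  rate <- mean(p < alpha)
  ci <- stats::qbinom(c(0.025, 0.975), n_species, alpha) / n_species
  list(rejection_rate = rate, interval = ci,
       within_interval = rate >= ci[1L] && rate <= ci[2L],
       n_species = n_species)
}
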