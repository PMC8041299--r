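#' The eight diet groups of the switch design
#'
#' Each group is an independent set of fish sampled once: unswitched
#' controls at day 0 (D0_FO, D0_VO) and fish sampled 1, 5/6 or 20 days
#' after switching from fish oil to vegetable oil (FOVO) or vice versa
#' (VOFO). The day-"5/6" groups are sampled at day 5 in freshwater and day
#' 6 in seawater but coded as one factor level.
#'
#' @return data.frame with columns \code{group}, \code{source}
#'   (pre-switch diet), \code{target} (post-switch diet) and
#'   \code{nominal_day}.
#' @export
diet_groups <- function() {
  data.frame(
    group = c("D0_FO", "D1_FOVO", "D5/6_FOVO", "D20_FOVO",
              "D0_VO", "D1_VOFO", "D5/6_VOFO", "D20_VOFO"),
    source = c("FO", "FO", "FO", "FO", "VO", "VO", "VO", "VO"),
    target = c("FO", "VO", "VO", "VO", "VO", "FO", "FO", "FO"),
    nominal_day = c("0", "1", "5/6", "20", "0", "1", "5/6", "20"),
    stringsAsFactors = FALSE
  )
}

#' Expected log2 abundance under exponential remodeling
#'
#' After a diet switch the expected log2 abundance relaxes exponentially
#' from the source diet's steady state toward the target's:
#' y(t) = y_target + (y_source - y_target) * exp(-k t). Kinetics act on the
#' log scale (multiplicative remodeling), consistent with a dilution-style
#' replacement of lipid pools and with log-normal measurement error.
#'
#' @param t Time since the switch, days.
#' @param y_source,y_target Steady-state log2 abundances on the source and
#'   target diets.
#' @param k Rate constant, 1/day (>= 0).
#' @return Expected log2 abundance. Vectorized over all arguments.
#' @export
remodeling_trajectory <- function(t, y_source, y_target, k) {
  stopifnot(all(k >= 0), all(t >= 0))
  y_target + (y_source - y_target) * exp(-k * t)
}

# log2-scale noise sd for a multiplicative (log-normal) CV
.sdlog2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Simulation configuration for a diet-switch lipidome experiment
#'
#' Defaults emulate the feeding-trial design: 3 tissues x 2 life stages x 8
#' diet groups x 4 fish (2 per tank x 2 tanks), about 300 lipid species
#' split over the five class blocks (TG 120, PC 80, PE 50, DG 20, Other
#' 30). Remodeling is faster in the gut of seawater fish; muscle turns over
#' slowest and has not reached the new steady state by day 20. Life-stage
#' offsets are concentrated in the phospholipids (PC/PE). Noise is
#' multiplicative with CV 0.15 plus a shared per-tank log2 offset.
#'
#' @param n_species Named integer vector of species per class block.
#' @param tissues,stages Design levels.
#' @param k Matrix of remodeling rate constants (1/day), rows = stages,
#'   columns = tissues.
#' @param diet_frac Fraction of species with a diet effect.
#' @param diet_effect_range Magnitude range (log2) of diet effects,
#'   uniform, random sign.
#' @param stage_frac Fraction of PC/PE species with a life-stage offset.
#' @param stage_offset Magnitude (log2) of the stage offset, random sign.
#' @param cv Multiplicative noise coefficient of variation.
#' @param tank_sd SD (log2) of the shared per-tank offset.
#' @param n_tanks,fish_per_tank Replication per cell (n = 4 by default).
#' @param base_log2 Named vector of class-level mean log2 baselines.
#' @param base_sd SD of per-species baselines around the class mean.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_species = c(TG = 120L, PC = 80L, PE = 50L,
                                     DG = 20L, Other = 30L),
                       tissues = c("gut", "liver", "muscle"),
                       stages = c("FW", "SW"),
                       k = matrix(c(0.25, 0.30, 0.05,
                                    1.00, 0.40, 0.06),
                                  nrow = 2L, byrow = TRUE,
                                  dimnames = list(c("FW", "SW"),
                                                  c("gut", "liver", "muscle"))),
                       diet_frac = 0.4, diet_effect_range = c(1, 3),
                       stage_frac = 0.3, stage_offset = 1.5,
                       cv = 0.15, tank_sd = 0.05,
                       n_tanks = 2L, fish_per_tank = 2L,
                       base_log2 = c(TG = 16, PC = 14, PE = 13,
                                     DG = 11, Other = 10),
                       base_sd = 1.5) {
  cfg <- list(n_species = n_species, tissues = tissues, stages = stages,
              k = k, diet_frac = diet_frac,
              diet_effect_range = diet_effect_range,
              stage_frac = stage_frac, stage_offset = stage_offset,
              cv = cv, tank_sd = tank_sd, n_tanks = n_tanks,
              fish_per_tank = fish_per_tank, base_log2 = base_log2,
              base_sd = base_sd)
  if (any(cfg$k < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (cfg$cv <= 0) stop("cv must be > 0", call. = FALSE)
  if (cfg$tank_sd < 0) stop("tank_sd must be >= 0", call. = FALSE)
  if (cfg$n_tanks < 1L || cfg$fish_per_tank < 1L) {
    stop("need at least one tank with at least one fish", call. = FALSE)
  }
  if (!all(cfg$stages %in% rownames(cfg$k)) ||
      !all(cfg$tissues %in% colnames(cfg$k))) {
    stop("k must have a row per stage and a column per tissue",
         call. = FALSE)
  }
  cfg$k <- cfg$k[cfg$stages, cfg$tissues, drop = FALSE]
  if (!all(names(cfg$n_species) %in% c("TG", "PC", "PE", "DG", "Other")) ||
      any(cfg$n_species < 1L)) {
    stop("n_species must cover the five blocks with positive counts",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# plausible shorthand names per block, deterministic given the RNG state
.generate_species_names <- function(n_species) {
  grids <- list(
    TG = expand.grid(class = "TG", carbons = seq(44L, 68L, 2L),
                     db = 0:18, stringsAsFactors = FALSE),
    PC = expand.grid(class = "PC", carbons = seq(30L, 44L, 2L),
                     db = 0:12, stringsAsFactors = FALSE),
    PE = expand.grid(class = "PE", carbons = seq(30L, 44L, 2L),
                     db = 0:12, stringsAsFactors = FALSE),
    DG = expand.grid(class = "DG", carbons = seq(28L, 44L, 2L),
                     db = 0:8, stringsAsFactors = FALSE),
    Other = expand.grid(class = c("SM", "CER", "LPC", "LPE", "MG", "CE"),
                        carbons = seq(14L, 42L, 2L),
                        db = 0:6, stringsAsFactors = FALSE)
  )
  out <- lapply(names(n_species), function(blk) {
    g <- grids[[blk]]
    g <- g[g$db <= pmax(1L, g$carbons %/% 4L), , drop = FALSE]
    pick <- g[sample.int(nrow(g), n_species[[blk]]), , drop = FALSE]
    data.frame(name = paste0(pick$class, "-", pick$carbons, ":", pick$db),
               class = pick$class, block = blk,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a synthetic diet-switch lipidome experiment
#'
#' Draws a full experiment from [sim_config()]: per species a baseline and
#' diet/stage effects, then per fish an abundance
#' 2^(trajectory + stage offset + tank offset + noise) following the
#' exponential remodeling model of [remodeling_trajectory()]. Identical
#' seeds give bit-identical output.
#'
#' @param config A \code{sim_config}.
#' @param seed Integer seed (mandatory).
#' @return List with \code{dataset} (a \code{lipidome_dataset} covering all
#'   tissues) and \code{truth} (per-species ground truth: steady states,
#'   effects, null labels; the rate-constant matrix rides along as an
#'   attribute).
#' @export
generate_experiment <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(seed)
  sp <- .generate_species_names(config$n_species)
  ns <- nrow(sp)
  base <- config$base_log2[sp$block] + stats::rnorm(ns, 0, config$base_sd)
  has_diet <- stats::runif(ns) < config$diet_frac
  diet_delta <- ifelse(
    has_diet,
    sample(c(-1, 1), ns, replace = TRUE) *
      stats::runif(ns, config$diet_effect_range[1L],
                   config$diet_effect_range[2L]),
    0
  )
  is_pl <- sp$block %in% c("PC", "PE")
  has_stage <- is_pl & stats::runif(ns) < config$stage_frac
  stage_off <- ifelse(has_stage,
                      sample(c(-1, 1), ns, replace = TRUE) *
                        config$stage_offset, 0)
  truth <- data.frame(
    name = sp$name, class = sp$class, block = sp$block,
    y_FO = base, y_VO = base + diet_delta, diet_delta = diet_delta,
    stage_offset = stage_off,
    diet_null = !has_diet, stage_null = !has_stage,
    stringsAsFactors = FALSE
  )
  attr(truth, "k") <- config$k
  attr(truth, "cv") <- config$cv

  dg <- diet_groups()
  # actual sampling day: the "5/6" groups are day 5 in FW, day 6 in SW
  actual_day <- function(nominal, stage) {
    out <- rep(NA_real_, length(nominal))
    mid <- nominal == "5/6"
    out[mid] <- ifelse(stage[mid] == "SW", 6, 5)
    out[!mid] <- as.numeric(nominal[!mid])
    out
  }
  meta <- expand.grid(fish = seq_len(config$fish_per_tank),
                      tank = seq_len(config$n_tanks),
                      diet_group = dg$group, stage = config$stages,
                      tissue = config$tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("tissue", "stage", "diet_group", "tank", "fish")]
  gidx <- match(meta$diet_group, dg$group)
  meta$day <- actual_day(dg$nominal_day[gidx], meta$stage)
  safe_group <- gsub("/", ".", meta$diet_group, fixed = TRUE)
  meta$sample_id <- paste(meta$tissue, meta$stage, safe_group,
                          paste0("T", meta$tank), paste0("F", meta$fish),
                          sep = "_")
  meta <- meta[, c("sample_id", "tissue", "stage", "diet_group", "day",
                   "tank", "fish")]

  # one shared log2 offset per (stage, diet group, tank), common to tissues:
  # the tank holds the fish, the tissues come from the same fish
  tank_key <- unique(paste(meta$stage, meta$diet_group, meta$tank, sep = "|"))
  tank_eff <- stats::setNames(stats::rnorm(length(tank_key), 0,
                                           config$tank_sd), tank_key)

  sdn <- .sdlog2(config$cv)
  nsam <- nrow(meta)
  y_src <- ifelse(dg$source[gidx] == "FO", 1, 0)  # 1 = FO source
  y_tgt <- ifelse(dg$target[gidx] == "FO", 1, 0)
  kvec <- config$k[cbind(meta$stage, meta$tissue)]
  decay <- exp(-kvec * meta$day)
  is_sw <- meta$stage == "SW"
  te <- tank_eff[paste(meta$stage, meta$diet_group, meta$tank, sep = "|")]

  ab <- matrix(0, nsam, ns, dimnames = list(meta$sample_id, truth$name))
  for (j in seq_len(ns)) {
    ys <- ifelse(y_src == 1, truth$y_FO[j], truth$y_VO[j])
    yt <- ifelse(y_tgt == 1, truth$y_FO[j], truth$y_VO[j])
    mu <- yt + (ys - yt) * decay + truth$stage_offset[j] * is_sw + te
    ab[, j] <- 2^(mu + stats::rnorm(nsam, 0, sdn))
  }
  list(dataset = lipidome_dataset(ab, meta,
                                  species = parse_lipid_names(truth$name)),
       truth = truth)
}

#' Expected log2 fold changes implied by the generator's own model
#'
#' Closed-form expectation table for benchmarking the differential module.
#' For the stage contrast (SW vs FW within one diet group) the expectation
#' is the planted stage offset plus any kinetic mismatch between stages
#' (different rate constants and the day-5 vs day-6 sampling). For the
#' diet-history contrast at a given day the expectation is the residual
#' separation (y_source - y_target) * exp(-k t).
#'
#' @param truth Truth table from [generate_experiment()].
#' @param contrast \code{"stage_within_group"} (default) or
#'   \code{"switched_vs_control"}.
#' @param tissue Tissue whose rate constants apply.
#' @param group Diet group (for \code{"stage_within_group"}).
#' @param stage Life stage and nominal day (for
#'   \code{"switched_vs_control"}).
#' @param day Nominal day, one of \code{"0"}, \code{"1"}, \code{"5/6"},
#'   \code{"20"}.
#' @return data.frame with \code{name} and \code{expected_log2FC}.
#' @export
truth_contrast_table <- function(truth,
                                 contrast = c("stage_within_group",
                                              "switched_vs_control"),
                                 tissue, group = "D0_FO", stage = "SW",
                                 day = "20") {
  contrast <- match.arg(contrast)
  k <- attr(truth, "k")
  if (is.null(k)) stop("truth table lacks its rate-constant attribute",
                       call. = FALSE)
  dg <- diet_groups()
  if (contrast == "stage_within_group") {
    g <- dg[dg$group == group, ]
    if (nrow(g) == 0L) stop("unknown diet group '", group, "'",
                            call. = FALSE)
    t_fw <- if (g$nominal_day == "5/6") 5 else as.numeric(g$nominal_day)
    t_sw <- if (g$nominal_day == "5/6") 6 else as.numeric(g$nominal_day)
    ys <- if (g$source == "FO") truth$y_FO else truth$y_VO
    yt <- if (g$target == "FO") truth$y_FO else truth$y_VO
    mu_sw <- remodeling_trajectory(t_sw, ys, yt, k["SW", tissue]) +
      truth$stage_offset
    mu_fw <- remodeling_trajectory(t_fw, ys, yt, k["FW", tissue])
    data.frame(name = truth$name, expected_log2FC = mu_sw - mu_fw,
               stringsAsFactors = FALSE)
  } else {
    if (day == "0") {
      return(data.frame(name = truth$name,
                        expected_log2FC = rep(0, nrow(truth)),
                        stringsAsFactors = FALSE))
    }
    t_act <- if (day == "5/6") (if (stage == "SW") 6 else 5) else
      as.numeric(day)
    kk <- k[stage, tissue]
    # switched (FOVO) fish at day t against the unswitched control already at
    # the target steady state: the residual separation decays as exp(-k t)
    mu_sw <- remodeling_trajectory(t_act, truth$y_FO, truth$y_VO, kk)
    data.frame(name = truth$name, expected_log2FC = mu_sw - truth$y_VO,
               stringsAsFactors = FALSE)
  }
}
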