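# --- logit-normal synthetic methylation generator -------------------------
#
# Emulates the cluster structure smoking leaves in blood methylation:
# "persistent" CpGs are shifted in everyone who ever smoked, "reverting"
# CpGs only in current smokers (they return to never-smoker levels after
# cessation), "partial" CpGs place former smokers part-way between, and
# "null" CpGs carry no signal. Former smokers therefore form an
# intermediate, overlapping cluster -- the situation a two-stage classifier
# is designed for.

#' Configure the synthetic methylation generator
#'
#' Per CpG a never-smoker mean beta is drawn uniformly from
#' `baseline_range`; class means follow the CpG's behaviour class
#' (persistent: shifted by the effect in current AND former; reverting:
#' shifted in current only; partial: shifted in current, and by
#' `former_fraction_partial` times the effect in former; null: identical
#' everywhere). Individual beta values are drawn on the logit scale around
#' the class mean with standard deviation `noise_sd` and transformed back,
#' so all values lie strictly inside (0, 1).
#'
#' Default effects are negative (smoking-associated hypomethylation, the
#' direction seen at AHRR), sized so that multi-CpG oracle scores separate
#' their target classes strongly while single CpGs overlap.
#'
#' @param n_current,n_former,n_never sample counts per class (default
#'   200 each).
#' @param n_persistent,n_reverting,n_partial,n_null CpG counts per
#'   behaviour class (defaults 50/50/50/350).
#' @param effect_persistent,effect_reverting,effect_partial signed mean
#'   beta shifts (default -0.15 each).
#' @param former_fraction_partial position of former smokers between never
#'   (0) and current (1) at partial CpGs, default 0.5.
#' @param noise_sd logit-scale standard deviation, default 0.5.
#' @param baseline_range interval within (0, 1) for never-smoker means,
#'   default `c(0.3, 0.8)`.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_current = 200, n_former = 200, n_never = 200,
                             n_persistent = 50, n_reverting = 50,
                             n_partial = 50, n_null = 350,
                             effect_persistent = -0.15,
                             effect_reverting = -0.15,
                             effect_partial = -0.15,
                             former_fraction_partial = 0.5,
                             noise_sd = 0.5,
                             baseline_range = c(0.3, 0.8), seed = 1) {
  cfg <- list(n_current = n_current, n_former = n_former, n_never = n_never,
              n_persistent = n_persistent, n_reverting = n_reverting,
              n_partial = n_partial, n_null = n_null,
              effect_persistent = effect_persistent,
              effect_reverting = effect_reverting,
              effect_partial = effect_partial,
              former_fraction_partial = former_fraction_partial,
              noise_sd = noise_sd, baseline_range = baseline_range,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_current", "n_former", "n_never", "n_persistent",
                         "n_reverting", "n_partial", "n_null")])
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts[4:7]) < 1) stop("need at least one CpG", call. = FALSE)
  if (sum(counts[1:3]) < 2) stop("need at least two samples", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (length(baseline_range) != 2L || baseline_range[1L] >= baseline_range[2L]
      || baseline_range[1L] <= 0 || baseline_range[2L] >= 1)
    stop("baseline_range must be an increasing interval inside (0, 1)",
         call. = FALSE)
  if (cfg$former_fraction_partial < 0 || cfg$former_fraction_partial > 1)
    stop("former_fraction_partial must lie in [0, 1]", call. = FALSE)
  effects <- unlist(cfg[c("effect_persistent", "effect_reverting",
                          "effect_partial")])
  lo <- baseline_range[1L] + min(0, min(effects))
  hi <- baseline_range[2L] + max(0, max(effects))
  if (lo <= 0 || hi >= 1)
    stop(sprintf(
      "shifted class means would leave (0, 1): range [%.3f, %.3f]", lo, hi),
      call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic beta matrix, sample sheet and truth table
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` when given.
#' @param truth optional truth table from a previous call: reuses that CpG
#'   universe (ids, behaviours and true class means) instead of drawing a
#'   fresh one, so a validation cohort shares the array and biology of its
#'   development cohort -- baseline methylation is a property of the CpG,
#'   not of the cohort. Only new samples are drawn.
#' @return list with elements `beta` (a [beta_matrix()]), `sheet` (a
#'   [sample_sheet()] data frame) and `truth` (a data frame with one row per
#'   CpG: `cpg_id`, `behaviour`, and the true class means `mean_never`,
#'   `mean_former`, `mean_current`). Deterministic given the seed.
#' @export
generate_methylation <- function(config, seed = config$seed, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())

  if (is.null(truth)) {
    behaviours <- rep(c("persistent", "reverting", "partial", "null"),
                      times = c(config$n_persistent, config$n_reverting,
                                config$n_partial, config$n_null))
    n_cpg <- length(behaviours)
    cpg_ids <- sprintf("cg%08d", seq_len(n_cpg))

    base <- stats::runif(n_cpg, config$baseline_range[1L],
                         config$baseline_range[2L])
    eff <- c(persistent = config$effect_persistent,
             reverting = config$effect_reverting,
             partial = config$effect_partial, null = 0)[behaviours]
    mean_never <- base
    mean_current <- base + eff
    mean_former <- base +
      ifelse(behaviours == "persistent", eff,
      ifelse(behaviours == "partial",
             config$former_fraction_partial * eff, 0))
  } else {
    need <- c("cpg_id", "behaviour", "mean_never", "mean_former",
              "mean_current")
    if (!all(need %in% names(truth)))
      stop("truth table must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    cpg_ids <- truth$cpg_id
    behaviours <- truth$behaviour
    n_cpg <- length(cpg_ids)
    mean_never <- truth$mean_never
    mean_former <- truth$mean_former
    mean_current <- truth$mean_current
  }

  status <- rep(c("current", "former", "never"),
                times = c(config$n_current, config$n_former, config$n_never))
  n_samp <- length(status)
  sample_ids <- sprintf("s%05d", seq_len(n_samp))

  mu <- cbind(current = mean_current, former = mean_former,
              never = mean_never)[, status, drop = FALSE]
  vals <- stats::plogis(stats::qlogis(mu) +
                        stats::rnorm(n_cpg * n_samp, sd = config$noise_sd))
  dim(vals) <- c(n_cpg, n_samp)
  dimnames(vals) <- list(cpg_ids, sample_ids)

  list(beta = beta_matrix(vals),
       sheet = sample_sheet(data.frame(sample_id = sample_ids,
                                       status = status,
                                       stringsAsFactors = FALSE)),
       truth = data.frame(cpg_id = cpg_ids, behaviour = behaviours,
                          mean_never = mean_never, mean_former = mean_former,
                          mean_current = mean_current,
                          stringsAsFactors = FALSE))
}

#' Named generator presets
#'
#' `paperlike-dev` and `paperlike-val` echo the class compositions of a
#' realistic development cohort (1063 samples: 364 current / 334 former /
#' 365 never) and external validation cohort (717 samples: 260 / 263 / 194).
#' `weak-former` raises `former_fraction_partial` towards 1 to emulate
#' recently-quit cohorts whose former smokers still look like current
#' smokers at partially-reverted sites.
#'
#' @return named list of [synthetic_config()] objects.
#' @export
synthetic_presets <- function() {
  list(
    "paperlike-dev" = synthetic_config(n_current = 364, n_former = 334,
                                       n_never = 365, seed = 101),
    "paperlike-val" = synthetic_config(n_current = 260, n_former = 263,
                                       n_never = 194, seed = 102),
    "weak-former" = synthetic_config(former_fraction_partial = 0.9,
                                     seed = 103))
}

#' Oracle score models from a generator truth table
#'
#' Builds the score a clairvoyant analyst would use: each CpG of the chosen
#' behaviour class weighted by its true between-class mean difference. For
#' `stage = "ever_never"` the persistent CpGs weighted by
#' (mean over ever smokers - never mean); for `stage = "current_former"` the
#' reverting CpGs weighted by (current mean - former mean). An
#' `"ahrr_like"` stage returns the single strongest persistent CpG with
#' unit-signed weight, the synthetic analogue of the one-site AHRR
#' reference.
#'
#' @param truth truth table from [generate_methylation()].
#' @param stage which separating axis to build.
#' @return a [score_model()].
#' @export
oracle_score_model <- function(truth,
                               stage = c("ever_never", "current_former",
                                         "ahrr_like")) {
  stage <- match.arg(stage)
  if (stage == "ever_never") {
    t <- truth[truth$behaviour == "persistent", , drop = FALSE]
    if (!nrow(t)) stop("truth table has no persistent CpGs", call. = FALSE)
    w <- (t$mean_current + t$mean_former) / 2 - t$mean_never
    return(score_model(t$cpg_id, w, name = "oracle-ever-never"))
  }
  if (stage == "current_former") {
    t <- truth[truth$behaviour == "reverting", , drop = FALSE]
    if (!nrow(t)) stop("truth table has no reverting CpGs", call. = FALSE)
    return(score_model(t$cpg_id, t$mean_current - t$mean_former,
                       name = "oracle-current-former"))
  }
  t <- truth[truth$behaviour == "persistent", , drop = FALSE]
  if (!nrow(t)) stop("truth table has no persistent CpGs", call. = FALSE)
  d <- t$mean_current - t$mean_never
  i <- which.max(abs(d))
  score_model(t$cpg_id[i], sign(d[i]), name = "oracle-ahrr-like")
}
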