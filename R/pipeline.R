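# --- end-to-end workflow: simulate -> cap -> select -> train -> validate --

#' Run the full development/validation workflow on synthetic data
#'
#' Executes the complete study-shaped pipeline: generate a development and a
#' validation cohort, optionally compute Riley parameter caps, derive the
#' two LASSO score models (ever/never on all development samples;
#' current/former on the self-reported ever smokers), train the two-stage
#' ternary classifier on the development cohort, then apply it -- thresholds
#' frozen -- to the validation cohort and evaluate: AUCs with DeLong
#' comparison against a single-CpG reference score, plus binary and ternary
#' confusion summaries.
#'
#' Artefacts are written under `out_dir` when given (classifier JSON,
#' prediction tables, evaluation reports), each stamped in the returned
#' provenance block with the config seed and the classifier file's MD5 hash
#' recorded both when written after training and re-read before validation,
#' making the frozen-threshold contract auditable.
#'
#' @param dev_config,val_config [synthetic_config()]s for the development
#'   and validation cohorts (defaults: the `paperlike-dev` / `paperlike-val`
#'   presets).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param use_riley_cap compute Riley caps from the development composition
#'   (with `r2_app` below) and cap the LASSO model sizes, default `TRUE`.
#' @param r2_app anticipated apparent R-squared for the Riley caps,
#'   default 0.609.
#' @param r2_scale scale of `r2_app`, see [riley_spec()].
#' @param lasso lasso settings template (a [lasso_spec()]); its seed and cap
#'   are overridden per stage.
#' @param reference_model [score_model()] used as the DeLong comparison
#'   reference; default the single-CpG oracle from the development truth.
#' @param out_dir optional directory for artefacts.
#' @return list of class `pipeline_result`: `classifier`, `models`,
#'   `riley`, `auc` (per stage: reference and lasso AUCs plus the DeLong
#'   comparison), `evaluation` (validation binary + ternary
#'   [confusion_summary()]s), `predictions`, and `provenance`.
#' @export
run_pipeline <- function(dev_config = synthetic_presets()[["paperlike-dev"]],
                         val_config = synthetic_presets()[["paperlike-val"]],
                         seed = 1, use_riley_cap = TRUE, r2_app = 0.609,
                         r2_scale = "nagelkerke", lasso = lasso_spec(),
                         reference_model = NULL, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, t_start) {
    message(sprintf("[%s] done in %.1fs", stage,
                    proc.time()[["elapsed"]] - t_start))
  }

  t <- proc.time()[["elapsed"]]
  dev <- generate_methylation(dev_config, seed = seed)
  # the validation cohort shares the CpG universe: new samples, same biology
  val <- generate_methylation(val_config, seed = seed + 1L,
                              truth = dev$truth)
  log_stage("simulate", t)

  status_dev <- stats::setNames(as.character(dev$sheet$status),
                                dev$sheet$sample_id)[colnames(dev$beta)]
  is_ever <- status_dev %in% c("current", "former")
  ever_idx <- which(is_ever)

  riley <- NULL
  cap_en <- cap_cf <- NULL
  if (use_riley_cap) {
    t <- proc.time()[["elapsed"]]
    n <- length(status_dev)
    riley <- list(
      ever_never = max_parameters(riley_spec(n, mean(is_ever), r2_app,
                                             r2_scale = r2_scale)),
      current_former = max_parameters(
        riley_spec(length(ever_idx),
                   mean(status_dev[ever_idx] == "current"), r2_app,
                   r2_scale = r2_scale)))
    cap_en <- riley$ever_never$p_max
    cap_cf <- riley$current_former$p_max
    log_stage("maxparams", t)
  }

  t <- proc.time()[["elapsed"]]
  spec_en <- lasso
  spec_en$seed <- as.integer(seed + 11L)
  spec_en$parameter_cap <- cap_en
  fit_en <- lasso_select(dev$beta, is_ever, spec = spec_en,
                         name = "lasso-ever-never")
  beta_ever <- beta_matrix(unclass(dev$beta)[, ever_idx, drop = FALSE])
  spec_cf <- lasso
  spec_cf$seed <- as.integer(seed + 12L)
  spec_cf$parameter_cap <- cap_cf
  fit_cf <- lasso_select(beta_ever, status_dev[ever_idx] == "current",
                         spec = spec_cf, name = "lasso-current-former")
  if (is.null(fit_en$model) || is.null(fit_cf$model))
    stop("stage 'select' failed: LASSO selected an empty model",
         call. = FALSE)
  log_stage("select", t)

  t <- proc.time()[["elapsed"]]
  clf <- train_ternary(dev$beta, dev$sheet, fit_en$model, fit_cf$model)
  log_stage("train", t)

  clf_hash_written <- clf_hash_applied <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    clf_path <- file.path(out_dir, "classifier.json")
    write_classifier(clf, clf_path)
    clf_hash_written <- unname(tools::md5sum(clf_path))
    # re-read before application: validation must use the frozen artefact
    clf <- read_classifier(clf_path)
    clf_hash_applied <- unname(tools::md5sum(clf_path))
  }

  t <- proc.time()[["elapsed"]]
  if (is.null(reference_model))
    reference_model <- oracle_score_model(dev$truth, "ahrr_like")
  status_val <- stats::setNames(as.character(val$sheet$status),
                                val$sheet$sample_id)[colnames(val$beta)]
  is_ever_val <- status_val %in% c("current", "former")
  ever_val <- which(is_ever_val)
  beta_ever_val <- beta_matrix(unclass(val$beta)[, ever_val, drop = FALSE])

  s_ref_en <- compute_score(val$beta, reference_model)
  s_las_en <- compute_score(val$beta, fit_en$model)
  s_ref_cf <- compute_score(beta_ever_val, reference_model)
  s_las_cf <- compute_score(beta_ever_val, fit_cf$model)
  auc_res <- list(
    ever_never = list(
      reference = roc_auc(s_ref_en, is_ever_val),
      lasso = roc_auc(s_las_en, is_ever_val),
      delong = delong_test(s_las_en, s_ref_en, is_ever_val)),
    current_former = list(
      reference = roc_auc(s_ref_cf, status_val[ever_val] == "current"),
      lasso = roc_auc(s_las_cf, status_val[ever_val] == "current"),
      delong = delong_test(s_las_cf, s_ref_cf,
                           status_val[ever_val] == "current")))

  pred <- apply_ternary(clf, val$beta)
  eval_ternary <- confusion_summary(pred, status_val,
                                    classes = smoking_levels)
  pred_binary <- ifelse(pred == "never", "never", "ever")
  actual_binary <- ifelse(status_val == "never", "never", "ever")
  eval_binary <- confusion_summary(pred_binary, actual_binary,
                                   classes = c("ever", "never"))
  log_stage("evaluate", t)

  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(sample_id = names(pred), predicted = pred,
                 actual = status_val),
      file.path(out_dir, "predictions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_report(eval_ternary, file.path(out_dir, "evaluation_ternary.json"))
    write_report(eval_binary, file.path(out_dir, "evaluation_binary.json"))
    write_score_model(fit_en$model, file.path(out_dir,
                                              "model_ever_never.tsv"))
    write_score_model(fit_cf$model, file.path(out_dir,
                                              "model_current_former.tsv"))
  }

  message(sprintf("[pipeline] total %.1fs",
                  proc.time()[["elapsed"]] - t0))
  structure(list(
    classifier = clf,
    models = list(ever_never = fit_en, current_former = fit_cf),
    riley = riley,
    auc = auc_res,
    evaluation = list(binary = eval_binary, ternary = eval_ternary),
    predictions = pred,
    provenance = list(seed = seed,
                      dev_seed = seed, val_seed = seed + 1L,
                      classifier_hash_written = clf_hash_written,
                      classifier_hash_applied = clf_hash_applied,
                      out_dir = out_dir)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  ever/never  AUC: lasso %.3f vs reference %.3f (DeLong p = %.3g)\n",
              x$auc$ever_never$lasso$auc, x$auc$ever_never$reference$auc,
              x$auc$ever_never$delong$p))
  cat(sprintf("  curr/former AUC: lasso %.3f vs reference %.3f (DeLong p = %.3g)\n",
              x$auc$current_former$lasso$auc,
              x$auc$current_former$reference$auc,
              x$auc$current_former$delong$p))
  cat(sprintf("  validation ternary accuracy %.3f (NIR %.3f, p = %.3g), kappa %.3f\n",
              x$evaluation$ternary$accuracy, x$evaluation$ternary$nir,
              x$evaluation$ternary$p_acc_gt_nir, x$evaluation$ternary$kappa))
  invisible(x)
}
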