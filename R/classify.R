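# --- binary rules and the two-stage ternary classifier --------------------

#' A binary classification rule: score model + oriented threshold
#'
#' Under `higher_is_case` a sample is labelled `case_label` when its score is
#' strictly greater than the threshold; under `lower_is_case`, strictly less.
#' A score exactly at the threshold goes to the control class (midpoint
#' thresholds make exact ties measure-zero in practice; the convention is
#' fixed so behaviour is deterministic).
#'
#' @param model a [score_model()].
#' @param threshold finite numeric cut-point in score units.
#' @param direction `"higher_is_case"` or `"lower_is_case"`.
#' @param case_label,control_label distinct class names.
#' @return object of class `binary_rule`.
#' @export
binary_rule <- function(model, threshold,
                        direction = c("higher_is_case", "lower_is_case"),
                        case_label = "case", control_label = "control") {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "score_model"))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (identical(case_label, control_label))
    stop("case and control labels must differ", call. = FALSE)
  structure(list(model = model, threshold = as.numeric(threshold),
                 direction = direction, case_label = case_label,
                 control_label = control_label),
            class = "binary_rule")
}

#' @export
print.binary_rule <- function(x, ...) {
  cat(sprintf("binary_rule: '%s' vs '%s' on score '%s' (%d CpGs)\n",
              x$case_label, x$control_label, x$model$name,
              length(x$model$cpgs)))
  cat(sprintf("  %s when score %s %.6g\n", x$case_label,
              if (x$direction == "higher_is_case") ">" else "<", x$threshold))
  invisible(x)
}

#' Apply a binary rule to a beta matrix
#'
#' @param rule a [binary_rule()].
#' @param beta a [beta_matrix()].
#' @param missing_policy forwarded to [compute_score()].
#' @return character vector of labels, named by sample.
#' @export
apply_binary <- function(rule, beta, missing_policy = "error") {
  stopifnot(inherits(rule, "binary_rule"))
  s <- compute_score(beta, rule$model, missing_policy = missing_policy)
  is_case <- if (rule$direction == "higher_is_case") s > rule$threshold
             else s < rule$threshold
  stats::setNames(ifelse(is_case, rule$case_label, rule$control_label),
                  names(s))
}

#' @export
predict.binary_rule <- function(object, newdata, ...) {
  apply_binary(object, newdata, ...)
}

#' Assemble a two-stage ternary smoking-status classifier
#'
#' Stage 1 separates ever (current or former) from never smokers; stage 2 is
#' applied only to the samples stage 1 calls ever, separating current from
#' former. Usually built by [train_ternary()] rather than directly.
#'
#' @param stage1 a [binary_rule()] with case `"ever"`, control `"never"`.
#' @param stage2 a [binary_rule()] with case `"current"`, control `"former"`.
#' @return object of class `ternary_classifier`.
#' @export
ternary_classifier <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "binary_rule"), inherits(stage2, "binary_rule"))
  if (stage1$case_label != "ever" || stage1$control_label != "never")
    stop("stage 1 must label ever vs never", call. = FALSE)
  if (stage2$case_label != "current" || stage2$control_label != "former")
    stop("stage 2 must label current vs former", call. = FALSE)
  structure(list(stage1 = stage1, stage2 = stage2),
            class = "ternary_classifier")
}

#' Train the two-stage ternary classifier
#'
#' Fits both thresholds on development data and freezes them. Stage 1 is fit
#' on all samples, ever (current + former) coded as cases against never
#' smokers. Stage 2 is fit on the subset of self-reported ever smokers,
#' current coded as cases against former. Thresholds minimise the Euclidean
#' distance to the ROC (0,1) corner; orientations are resolved per score
#' (`"auto"`) at training time and stored -- they are never re-learned when
#' the classifier is applied to new data.
#'
#' Note the deliberate asymmetry: stage 2 is *trained* on self-reported ever
#' smokers but *applied* to stage-1-predicted ever smokers.
#'
#' @param beta development [beta_matrix()].
#' @param sheet a [sample_sheet()] covering the beta matrix's samples.
#' @param model_ever [score_model()] for the ever-vs-never score.
#' @param model_cf [score_model()] for the current-vs-former score.
#' @param missing_policy forwarded to [compute_score()].
#' @return a [ternary_classifier()] with frozen thresholds.
#' @export
train_ternary <- function(beta, sheet, model_ever, model_cf,
                          missing_policy = "error") {
  sheet <- sample_sheet(sheet)
  missing <- setdiff(colnames(beta), sheet$sample_id)
  if (length(missing))
    stop("sample(s) absent from sample sheet: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  status <- stats::setNames(as.character(sheet$status), sheet$sample_id)
  status <- status[colnames(beta)]
  for (cls in smoking_levels)
    if (!any(status == cls))
      stop("training data contain no '", cls, "' samples", call. = FALSE)

  # stage 1: ever vs never over all samples
  s_ever <- compute_score(beta, model_ever, missing_policy = missing_policy)
  is_ever <- status %in% c("current", "former")
  roc1 <- build_roc(s_ever, is_ever, direction = "auto")
  thr1 <- optimal_threshold(roc1)
  stage1 <- binary_rule(model_ever, thr1, roc1$direction,
                        case_label = "ever", control_label = "never")

  # stage 2: current vs former over self-reported ever smokers only
  keep <- which(is_ever)
  sub <- beta_matrix(unclass(beta)[, keep, drop = FALSE])
  s_cf <- compute_score(sub, model_cf, missing_policy = missing_policy)
  roc2 <- build_roc(s_cf, status[keep] == "current", direction = "auto")
  thr2 <- optimal_threshold(roc2)
  stage2 <- binary_rule(model_cf, thr2, roc2$direction,
                        case_label = "current", control_label = "former")

  ternary_classifier(stage1, stage2)
}

#' Apply a ternary classifier
#'
#' Stage 1 assigns never (final) or ever; stage 2 splits the predicted ever
#' smokers into current and former. Every sample receives exactly one label.
#'
#' @param clf a [ternary_classifier()].
#' @param beta a [beta_matrix()].
#' @param missing_policy forwarded to [compute_score()].
#' @return character vector over `{current, former, never}`, named by sample.
#' @export
apply_ternary <- function(clf, beta, missing_policy = "error") {
  stopifnot(inherits(clf, "ternary_classifier"))
  lab1 <- apply_binary(clf$stage1, beta, missing_policy)
  out <- stats::setNames(rep("never", ncol(beta)), colnames(beta))
  ever_idx <- which(lab1 == "ever")
  if (length(ever_idx)) {
    sub <- beta_matrix(unclass(beta)[, ever_idx, drop = FALSE])
    out[ever_idx] <- apply_binary(clf$stage2, sub, missing_policy)
  }
  out
}

#' @export
predict.ternary_classifier <- function(object, newdata, ...) {
  apply_ternary(object, newdata, ...)
}

#' @export
print.ternary_classifier <- function(x, ...) {
  cat("ternary_classifier (two-stage: ever/never, then current/former)\n")
  cat("stage 1: ")
  print(x$stage1)
  cat("stage 2 (applied to predicted ever smokers): ")
  print(x$stage2)
  invisible(x)
}

#' @export
summary.ternary_classifier <- function(object, ...) {
  cat(sprintf(
    "Two-stage ternary smoking classifier\n  stage 1 '%s': %d CpGs, threshold %.6g (%s)\n  stage 2 '%s': %d CpGs, threshold %.6g (%s)\n",
    object$stage1$model$name, length(object$stage1$model$cpgs),
    object$stage1$threshold, object$stage1$direction,
    object$stage2$model$name, length(object$stage2$model$cpgs),
    object$stage2$threshold, object$stage2$direction))
  invisible(object)
}

#' @export
coef.ternary_classifier <- function(object, ...) {
  list(stage1 = coef(object$stage1$model), stage2 = coef(object$stage2$model))
}

.rule_to_list <- function(r) {
  list(model = .model_to_list(r$model), threshold = r$threshold,
       direction = r$direction, case_label = r$case_label,
       control_label = r$control_label)
}

.rule_from_list <- function(l) {
  binary_rule(.model_from_list(l$model), as.numeric(l$threshold),
              l$direction, l$case_label, l$control_label)
}

#' Serialise a classifier to self-contained JSON
#'
#' The file embeds both score models in full, so a classifier file can be
#' applied anywhere without its training artefacts.
#'
#' @param clf a [ternary_classifier()] or [binary_rule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(clf, path) {
  obj <- if (inherits(clf, "ternary_classifier")) {
    list(type = "ternary_classifier", stage1 = .rule_to_list(clf$stage1),
         stage2 = .rule_to_list(clf$stage2))
  } else if (inherits(clf, "binary_rule")) {
    list(type = "binary_rule", rule = .rule_to_list(clf))
  } else stop("not a classifier", call. = FALSE)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path)
  switch(obj$type,
    ternary_classifier = ternary_classifier(.rule_from_list(obj$stage1),
                                            .rule_from_list(obj$stage2)),
    binary_rule = .rule_from_list(obj$rule),
    stop("unrecognised classifier file", call. = FALSE))
}
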