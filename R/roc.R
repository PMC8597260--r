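# --- ROC construction, AUC, DeLong variance and paired comparison ---------
#
# AUC follows the Mann-Whitney convention: P(score_case > score_control)
# + 0.5 * P(tie). Variances use DeLong's structural components, computed by
# the rank trick (midranks within cases/controls vs. overall), which is
# algebraically identical to averaging the pairwise kernel.

# coerce labels + case designation to a logical is-case vector
.as_case <- function(labels, case = NULL) {
  if (is.logical(labels)) {
    if (!is.null(case)) stop("'case' is ignored for logical labels",
                             call. = FALSE)
    is_case <- labels
  } else {
    labels <- as.character(labels)
    if (is.null(case)) {
      lev <- sort(unique(labels))
      if (length(lev) != 2L)
        stop("'case' must be given unless labels are logical or two-valued",
             call. = FALSE)
      case <- lev[2L]
    }
    is_case <- labels == case
  }
  if (anyNA(is_case)) stop("labels contain NA", call. = FALSE)
  if (!any(is_case) || all(is_case))
    stop("need at least one case and one control", call. = FALSE)
  is_case
}

# Mann-Whitney AUC for higher-is-case via midranks
.mw_auc <- function(scores, is_case) {
  m <- sum(is_case)
  n <- sum(!is_case)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_case]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components for higher-is-case oriented scores:
# v10[i] = mean_j psi(X_i, Y_j), v01[j] = mean_i psi(X_i, Y_j)
.delong_components <- function(scores, is_case) {
  x <- scores[is_case]
  y <- scores[!is_case]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  auc <- sum(r_all[seq_len(m)] - rx) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

.delong_var <- function(comp) {
  s10 <- if (comp$m > 1L) stats::var(comp$v10) else 0
  s01 <- if (comp$n > 1L) stats::var(comp$v01) else 0
  s10 / comp$m + s01 / comp$n
}

.resolve_direction <- function(scores, is_case, direction) {
  if (direction != "auto") return(direction)
  if (.mw_auc(scores, is_case) >= 0.5) "higher_is_case" else "lower_is_case"
}

# orient so that higher score = case
.orient <- function(scores, direction) {
  if (direction == "lower_is_case") -scores else scores
}

#' Build a ROC curve over all candidate thresholds
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores, plus -Inf and +Inf sentinels (the all-case and no-case operating
#' points). Under `higher_is_case` a sample is called a case when its score
#' is strictly above the threshold; under `lower_is_case`, strictly below.
#' `direction = "auto"` picks the orientation whose AUC is at least 0.5 --
#' needed because smoking lowers methylation at sites like cg05575921, so a
#' raw AHRR score places cases below the threshold.
#'
#' @param scores numeric score vector.
#' @param labels case/control labels: logical (TRUE = case), or any
#'   two-valued vector with `case` naming the case level.
#' @param case the label value counted as "case" (coded 1 in the paper
#'   sense); required unless `labels` is logical or has exactly two values
#'   (then the later sorted value is the case).
#' @param direction `"auto"`, `"higher_is_case"` or `"lower_is_case"`.
#' @return object of class `roc_curve` with fields `thresholds`,
#'   `sensitivities`, `specificities`, `direction`, `n_case`, `n_control`.
#' @export
build_roc <- function(scores, labels, case = NULL,
                      direction = c("auto", "higher_is_case",
                                    "lower_is_case")) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  if (anyNA(scores) || !all(is.finite(scores)))
    stop("scores must be finite and non-missing", call. = FALSE)
  is_case <- .as_case(labels, case)
  if (length(scores) != length(is_case))
    stop("scores and labels differ in length", call. = FALSE)
  direction <- .resolve_direction(scores, is_case, direction)

  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
  xs <- sort(scores[is_case])
  ys <- sort(scores[!is_case])
  m <- length(xs)
  n <- length(ys)
  if (direction == "higher_is_case") {
    sens <- (m - findInterval(thr, xs)) / m          # P(X > t)
    spec <- findInterval(thr, ys) / n                # P(Y <= t)
  } else {
    sens <- findInterval(thr, xs, left.open = TRUE) / m       # P(X < t)
    spec <- (n - findInterval(thr, ys, left.open = TRUE)) / n # P(Y >= t)
  }
  structure(list(thresholds = thr, sensitivities = sens,
                 specificities = spec, direction = direction,
                 n_case = m, n_control = n),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, %d cases / %d controls, %s\n",
              length(x$thresholds), x$n_case, x$n_control, x$direction))
  invisible(x)
}

#' AUC with DeLong variance and confidence interval
#'
#' AUC is the Mann-Whitney concordance (ties count one half). The variance is
#' DeLong's structural-components estimate and the confidence interval is the
#' normal approximation on the AUC scale, truncated to \[0, 1\].
#'
#' @inheritParams build_roc
#' @param conf_level confidence level, default 0.95.
#' @return object of class `auc_result`: `auc`, `variance`, `ci95`
#'   (length-2 vector), `direction`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels, case = NULL,
                    direction = c("auto", "higher_is_case", "lower_is_case"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  is_case <- .as_case(labels, case)
  if (length(scores) != length(is_case))
    stop("scores and labels differ in length", call. = FALSE)
  direction <- .resolve_direction(scores, is_case, direction)
  comp <- .delong_components(.orient(scores, direction), is_case)
  v <- .delong_var(comp)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(comp$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  structure(list(auc = comp$auc, variance = v, ci95 = ci,
                 direction = direction, n_case = comp$m, n_control = comp$n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f-%.4f), DeLong variance %.3g, %s\n",
              x$auc, x$ci95[1L], x$ci95[2L], x$variance, x$direction))
  invisible(x)
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Tests whether two scores measured on the same samples discriminate the
#' same labels equally well, using the covariance of the DeLong structural
#' components. Each score is first oriented case-high according to its own
#' direction (resolved per score when `"auto"`).
#'
#' @param scores_a,scores_b numeric score vectors over identical samples. If
#'   both are named, `scores_b` is aligned to the names of `scores_a`.
#' @inheritParams build_roc
#' @param direction_a,direction_b orientation for each score.
#' @return object of class `delong_comparison`: `z`, `p` (two-sided),
#'   `auc_a`, `auc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels, case = NULL,
                        direction_a = "auto", direction_b = "auto") {
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    if (!setequal(names(scores_a), names(scores_b)))
      stop("score vectors cover different sample sets", call. = FALSE)
    scores_b <- scores_b[names(scores_a)]
  }
  scores_a <- as.numeric(scores_a)
  scores_b <- as.numeric(scores_b)
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length", call. = FALSE)
  is_case <- .as_case(labels, case)
  if (length(scores_a) != length(is_case))
    stop("scores and labels differ in length", call. = FALSE)
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  da <- .resolve_direction(scores_a, is_case, direction_a)
  db <- .resolve_direction(scores_b, is_case, direction_b)
  ca <- .delong_components(.orient(scores_a, da), is_case)
  cb <- .delong_components(.orient(scores_b, db), is_case)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / ca$m +
              (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / ca$n
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
    if (abs(d) > 1e-12)
      warning("zero variance for a non-zero AUC difference", call. = FALSE)
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(z = z, p = p, auc_a = ca$auc, auc_b = cb$auc,
                 direction_a = da, direction_b = db),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong Z-test: AUC_a %.4f vs AUC_b %.4f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Optimal classification threshold (closest to the (0,1) corner)
#'
#' Returns the candidate threshold minimising the Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` between its ROC operating point and
#' the top-left corner. Ties are broken towards the smallest threshold.
#'
#' @param curve a [build_roc()] result.
#' @return a single numeric threshold in score units.
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!any(is.finite(curve$thresholds)))
    stop("all scores equal: the score is uninformative, no threshold exists",
         call. = FALSE)
  d <- sqrt((1 - curve$sensitivities)^2 + (1 - curve$specificities)^2)
  # thresholds ascend, so the first minimiser is the smallest threshold
  curve$thresholds[which.min(d)]
}
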