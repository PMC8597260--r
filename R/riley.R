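# --- Riley criteria: maximum number of score parameters -------------------
#
# For a binary-outcome prediction score developed on n samples with outcome
# proportion phi and an anticipated apparent R^2, three criteria bound the
# model: (1) expected global shrinkage S >= 0.9; (2) small absolute optimism
# in Nagelkerke's R^2 (<= 0.05 by default); (3) precise estimation of the
# outcome proportion itself (margin of error <= 0.05). Criteria 1 and 2
# bound the number of parameters p; criterion 3 constrains n only and is
# reported as a feasibility flag.

#' Specify inputs for the Riley maximum-parameter calculation
#'
#' @param n development sample count (>= 2).
#' @param phi outcome proportion, strictly inside (0, 1).
#' @param r2_app anticipated apparent R-squared of the score, in (0, 1).
#' @param r2_scale scale of `r2_app`: `"nagelkerke"` (default; converted to
#'   the Cox-Snell scale by multiplying by the attainable maximum Cox-Snell
#'   R-squared) or `"cox_snell"` (used as is, the input convention of the
#'   pmsampsize software).
#' @param shrinkage_target expected global shrinkage factor bound, default 0.9.
#' @param optimism_delta absolute Nagelkerke R-squared optimism bound,
#'   default 0.05.
#' @param margin margin of error for the outcome proportion, default 0.05.
#' @param z normal quantile for the margin criterion, default 1.96.
#' @return object of class `riley_spec`.
#' @export
riley_spec <- function(n, phi, r2_app,
                       r2_scale = c("nagelkerke", "cox_snell"),
                       shrinkage_target = 0.9, optimism_delta = 0.05,
                       margin = 0.05, z = 1.96) {
  r2_scale <- match.arg(r2_scale)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (phi <= 0 || phi >= 1)
    stop("phi must lie strictly inside (0, 1)", call. = FALSE)
  if (r2_app <= 0 || r2_app >= 1)
    stop("r2_app must lie strictly inside (0, 1)", call. = FALSE)
  if (shrinkage_target <= 0 || shrinkage_target >= 1)
    stop("shrinkage_target must lie strictly inside (0, 1)", call. = FALSE)
  if (optimism_delta <= 0) stop("optimism_delta must be positive",
                                call. = FALSE)
  structure(list(n = as.numeric(n), phi = phi, r2_app = r2_app,
                 r2_scale = r2_scale, shrinkage_target = shrinkage_target,
                 optimism_delta = optimism_delta, margin = margin, z = z),
            class = "riley_spec")
}

#' Maximum number of score parameters under the Riley criteria
#'
#' Computes, for a binary outcome, the largest integer parameter count
#' satisfying the shrinkage criterion and the optimism criterion, plus the
#' feasibility of the margin-of-error criterion. All intermediates (null
#' log-likelihood, attainable maximum Cox-Snell R-squared, apparent
#' Cox-Snell R-squared, the optimism-implied shrinkage) are returned for
#' audit.
#'
#' The bounds are `p <= n (S - 1) ln(1 - R2_cs / S)` with `S` the shrinkage
#' target (criterion 1) and, for criterion 2, `S` replaced by
#' `R2_cs / (R2_cs + delta * maxR2_cs)`. Bounds are floored (conservative).
#'
#' @param spec a [riley_spec()].
#' @return object of class `riley_result` with integer fields
#'   `p_crit_shrinkage`, `p_crit_optimism`, `p_max`, logical `margin_ok`,
#'   `n_margin_required`, and an `intermediates` list.
#' @examples
#' max_parameters(riley_spec(1063, 0.66, 0.609, r2_scale = "cox_snell"))$p_max
#' @export
max_parameters <- function(spec) {
  stopifnot(inherits(spec, "riley_spec"))
  n <- spec$n
  phi <- spec$phi
  lnL_null <- n * (phi * log(phi) + (1 - phi) * log(1 - phi))
  max_r2cs <- 1 - exp(2 * lnL_null / n)
  r2cs <- if (spec$r2_scale == "nagelkerke") spec$r2_app * max_r2cs
          else spec$r2_app
  if (r2cs >= max_r2cs + 1e-12)
    stop("apparent Cox-Snell R-squared exceeds its attainable maximum",
         call. = FALSE)

  bound <- function(S) {
    if (r2cs >= S) return(Inf)  # formula breaks down; shrinkage unattainable
    n * (S - 1) * log(1 - r2cs / S)
  }
  p1 <- bound(spec$shrinkage_target)
  s2 <- r2cs / (r2cs + spec$optimism_delta * max_r2cs)
  p2 <- bound(s2)

  n_margin <- spec$z^2 * phi * (1 - phi) / spec$margin^2
  res <- list(
    p_crit_shrinkage = floor(p1),
    p_crit_optimism = floor(p2),
    p_max = floor(min(p1, p2)),
    margin_ok = n >= n_margin,
    n_margin_required = n_margin,
    intermediates = list(lnL_null = lnL_null, max_r2cs = max_r2cs,
                         r2cs_app = r2cs, shrinkage_optimism = s2,
                         p_shrinkage_raw = p1, p_optimism_raw = p2))
  class(res) <- "riley_result"
  res
}

#' @export
print.riley_result <- function(x, ...) {
  i <- x$intermediates
  cat("Riley maximum-parameter audit\n")
  cat(sprintf("  null log-likelihood      %.4f\n", i$lnL_null))
  cat(sprintf("  max Cox-Snell R2         %.6f\n", i$max_r2cs))
  cat(sprintf("  apparent Cox-Snell R2    %.6f\n", i$r2cs_app))
  cat(sprintf("  criterion 1 (shrinkage)  p <= %.2f -> %d\n",
              i$p_shrinkage_raw, x$p_crit_shrinkage))
  cat(sprintf("  criterion 2 (optimism)   S = %.6f, p <= %.2f -> %d\n",
              i$shrinkage_optimism, i$p_optimism_raw, x$p_crit_optimism))
  cat(sprintf("  criterion 3 (margin)     n required %.1f -> %s\n",
              x$n_margin_required, if (x$margin_ok) "satisfied" else "NOT met"))
  cat(sprintf("  maximum parameters       %d\n", x$p_max))
  invisible(x)
}
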