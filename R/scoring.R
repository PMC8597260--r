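#' Compute DNAm classification scores
#'
#' Applies a weighted-CpG score model to a beta matrix: for each sample the
#' score is the intercept plus the sum over model terms of
#' `weight_j * beta(cpg_j, sample)`. Weights apply to beta values on the
#' 0-1 fraction scale.
#'
#' Missing beta cells are handled by `missing_policy`: under `"error"`
#' (default) any missing value at a model CpG aborts; under `"mean_impute"` a
#' missing cell is replaced by the mean of the non-missing values of that CpG
#' across the supplied samples (an error if a model CpG is entirely missing).
#'
#' @param beta a [beta_matrix()].
#' @param model a [score_model()].
#' @param missing_policy `"error"` or `"mean_impute"`.
#' @return named numeric vector of scores, one per sample, in the beta
#'   matrix's sample order.
#' @examples
#' b <- beta_matrix(matrix(c(0.4, 0.1), 2, 1,
#'                         dimnames = list(c("cgA", "cgB"), "s1")))
#' compute_score(b, score_model(c("cgA", "cgB"), c(0.5, -2)))  # 0.0
#' @export
compute_score <- function(beta, model,
                          missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(beta, "beta_matrix"), inherits(model, "score_model"))
  absent <- setdiff(model$cpgs, rownames(beta))
  if (length(absent))
    stop("model CpG(s) absent from beta matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  sub <- unclass(beta)[model$cpgs, , drop = FALSE]
  if (anyNA(sub)) {
    if (missing_policy == "error") {
      i <- arrayInd(which(is.na(sub))[1L], dim(sub))
      stop(sprintf("missing beta at CpG '%s', sample '%s' (policy = 'error')",
                   model$cpgs[i[1L]], colnames(sub)[i[2L]]), call. = FALSE)
    }
    row_means <- rowMeans(sub, na.rm = TRUE)
    dead <- which(is.nan(row_means))
    if (length(dead))
      stop("CpG(s) with all values missing cannot be mean-imputed: ",
           paste(model$cpgs[dead], collapse = ", "), call. = FALSE)
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    sub[na_idx] <- row_means[na_idx[, 1L]]
  }
  scores <- as.numeric(model$intercept + crossprod(sub, model$weights))
  stats::setNames(scores, colnames(sub))
}
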