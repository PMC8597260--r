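# --- cross-validated LASSO score derivation -------------------------------

#' Specify a cross-validated LASSO feature-selection run
#'
#' @param k_folds number of CV folds, default 5.
#' @param n_lambda length of the automatically generated lambda sequence,
#'   default 100.
#' @param seed integer seed controlling the (class-stratified) fold
#'   assignment.
#' @param candidate_cpgs optional CpG id vector restricting the predictors;
#'   `NULL` means all CpGs in the beta matrix.
#' @param parameter_cap optional integer cap on the number of selected CpGs
#'   (for example a [max_parameters()] bound); when the minimum-CV-error
#'   lambda selects more, the smallest lambda whose selection respects the
#'   cap is used instead and the substitution is flagged.
#' @param standardize standardise predictors inside the fit (coefficients
#'   are always reported back on the raw beta scale), default `FALSE` so the
#'   exported weights apply directly to beta fractions.
#' @return object of class `lasso_spec`.
#' @export
lasso_spec <- function(k_folds = 5, n_lambda = 100, seed = 1,
                       candidate_cpgs = NULL, parameter_cap = NULL,
                       standardize = FALSE) {
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  if (n_lambda < 2) stop("n_lambda must be >= 2", call. = FALSE)
  structure(list(k_folds = as.integer(k_folds),
                 n_lambda = as.integer(n_lambda), seed = as.integer(seed),
                 candidate_cpgs = candidate_cpgs,
                 parameter_cap = parameter_cap,
                 standardize = isTRUE(standardize)),
            class = "lasso_spec")
}

# local RNG that leaves the global stream untouched
.seeded_rng <- function(seed) {
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
  set.seed(seed)
  on_done <- function() {
    if (is.null(state)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", state, envir = globalenv())
  }
  list(permute = function(n) sample.int(n),
       restore = on_done)
}

#' L1-penalised logistic feature selection with cross-validated lambda
#'
#' Fits an L1-penalised logistic regression path over `n_lambda` values
#' (log-spaced down from the smallest lambda giving the empty model),
#' selects the lambda minimising mean cross-validated binomial deviance over
#' `k_folds` class-stratified folds, and returns the nonzero coefficients as
#' a [score_model()] (intercept included). The penalised path and CV are
#' delegated to glmnet -- the software the original score derivations used.
#'
#' @param beta a [beta_matrix()] (no missing values).
#' @param labels binary labels over the beta matrix's samples.
#' @param case label value coded as the case class (see [build_roc()]).
#' @param spec a [lasso_spec()].
#' @param name label for the returned score model.
#' @return list of class `lasso_fit`: `model` (the [score_model()]),
#'   `diagnostics` (lambda grid, per-lambda mean CV deviance and nonzero
#'   counts, chosen lambda, cap substitution flag, standardize flag) and
#'   `glmnet_fit` (the underlying cv.glmnet object).
#' @export
lasso_select <- function(beta, labels, case = NULL, spec = lasso_spec(),
                         name = "lasso") {
  stopifnot(inherits(beta, "beta_matrix"), inherits(spec, "lasso_spec"))
  is_case <- .as_case(labels, case)
  if (length(is_case) != ncol(beta))
    stop("labels and beta matrix samples differ in length", call. = FALSE)
  cpgs <- spec$candidate_cpgs
  if (is.null(cpgs)) {
    cpgs <- rownames(beta)
  } else {
    absent <- setdiff(cpgs, rownames(beta))
    if (length(absent))
      stop("candidate CpG(s) absent from beta matrix: ",
           paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  x <- t(unclass(beta)[cpgs, , drop = FALSE])
  if (anyNA(x)) stop("beta matrix contains missing values; impute first",
                     call. = FALSE)

  rng <- .seeded_rng(spec$seed)
  foldid <- .stratified_folds_given(is_case, spec$k_folds, rng)
  rng$restore()

  cv <- glmnet::cv.glmnet(x, factor(is_case, levels = c(FALSE, TRUE)),
                          family = "binomial", alpha = 1,
                          nlambda = spec$n_lambda, foldid = foldid,
                          type.measure = "deviance",
                          standardize = spec$standardize)
  lambda_sel <- cv$lambda.min
  cap_applied <- FALSE
  if (!is.null(spec$parameter_cap)) {
    nz_min <- cv$nzero[cv$lambda == lambda_sel]
    if (nz_min > spec$parameter_cap) {
      ok <- which(cv$nzero <= spec$parameter_cap)
      if (!length(ok))
        stop("no lambda on the path satisfies the parameter cap",
             call. = FALSE)
      # lambdas descend along the path; the last admissible one is smallest
      lambda_sel <- min(cv$lambda[ok])
      cap_applied <- TRUE
    }
  }
  co <- stats::coef(cv$glmnet.fit, s = lambda_sel)
  co <- as.matrix(co)[, 1L]
  nz <- co[-1L][co[-1L] != 0]
  model <- if (length(nz))
    score_model(names(nz), unname(nz), intercept = unname(co[1L]),
                name = name)
  else NULL

  structure(list(
    model = model,
    diagnostics = list(lambda = cv$lambda, cv_error = cv$cvm,
                       nonzero = as.integer(cv$nzero),
                       lambda_min = cv$lambda.min,
                       lambda_selected = lambda_sel,
                       cap_applied = cap_applied,
                       n_selected = length(nz),
                       standardize = spec$standardize,
                       seed = spec$seed, k_folds = spec$k_folds),
    glmnet_fit = cv), class = "lasso_fit")
}

# fold assignment using an already-seeded rng closure
.stratified_folds_given <- function(is_case, k, rng) {
  fold <- integer(length(is_case))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_case == cls)
    idx <- idx[rng$permute(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @export
print.lasso_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "lasso_fit: %d CpGs selected at lambda %.5g (%d-fold CV, seed %d)%s\n",
    d$n_selected, d$lambda_selected, d$k_folds, d$seed,
    if (d$cap_applied) " [parameter cap applied]" else ""))
  invisible(x)
}
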