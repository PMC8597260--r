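#' Construct a weighted CpG classification score model
#'
#' A score model is an ordered set of (CpG, weight) terms plus an intercept.
#' Applied to a beta matrix it yields, per sample, the DNAm classification
#' score `intercept + sum_j weight_j * beta(cpg_j, sample)`. The single-CpG
#' AHRR model is the degenerate case with one unit-weight term (see
#' [ahrr_model()]).
#'
#' @param cpgs character vector of unique CpG ids.
#' @param weights numeric vector of finite signed weights, one per CpG.
#' @param intercept numeric scalar, default 0.
#' @param name label for the model.
#' @return object of class `score_model`.
#' @examples
#' m <- score_model(c("cg01", "cg02"), c(0.5, -2), name = "toy")
#' coef(m)
#' @export
score_model <- function(cpgs, weights, intercept = 0, name = "score") {
  cpgs <- as.character(cpgs)
  weights <- as.numeric(weights)
  if (length(cpgs) < 1L) stop("a score model needs at least one term",
                              call. = FALSE)
  if (length(cpgs) != length(weights))
    stop("cpgs and weights differ in length", call. = FALSE)
  if (anyDuplicated(cpgs))
    stop("duplicate CpG in model terms: ", cpgs[duplicated(cpgs)][1L],
         call. = FALSE)
  if (!all(is.finite(weights)))
    stop("model weights must be finite", call. = FALSE)
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  structure(list(name = as.character(name)[1L], cpgs = cpgs,
                 weights = weights, intercept = as.numeric(intercept)[1L]),
            class = "score_model")
}

#' The single-CpG AHRR reference model
#'
#' Methylation at cg05575921 (AHRR) with unit weight: the field's standard
#' single-site smoking biomarker, used throughout as the reference score.
#' @return a [score_model()] with one term.
#' @export
ahrr_model <- function() score_model("cg05575921", 1.0, name = "AHRR")

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model '%s': %d CpG term(s), intercept %g\n",
              x$name, length(x$cpgs), x$intercept))
  show <- utils::head(seq_along(x$cpgs), 10L)
  for (i in show) cat(sprintf("  %-12s %+ .6g\n", x$cpgs[i], x$weights[i]))
  if (length(x$cpgs) > 10L) cat(sprintf("  ... %d more\n", length(x$cpgs) - 10L))
  invisible(x)
}

#' @export
coef.score_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights),
                  c("(Intercept)", object$cpgs))
}

# reserved id flagging an intercept row in coefficient tables
.INTERCEPT_ID <- "(Intercept)"

#' Read a score model from a two-column coefficient table
#'
#' The file is a delimited table with columns `cpg_id` and `weight`
#' (header required). A row whose id is `(Intercept)` sets the intercept.
#'
#' @param path file path (TSV or CSV by extension).
#' @param name model label; defaults to the file name.
#' @return a [score_model()] with terms in file order.
#' @export
read_score_model <- function(path, name = NULL) {
  df <- .read_delim_table(path)
  if (ncol(df) < 2L)
    stop("score model table needs two columns (cpg_id, weight)", call. = FALSE)
  ids <- as.character(df[[1L]])
  w <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1L]
    stop(sprintf("missing or non-numeric weight at row %d ('%s')",
                 bad, ids[bad]), call. = FALSE)
  }
  is_int <- ids == .INTERCEPT_ID
  if (sum(is_int) > 1L) stop("multiple intercept rows", call. = FALSE)
  intercept <- if (any(is_int)) w[is_int] else 0
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  score_model(ids[!is_int], w[!is_int], intercept = intercept, name = name)
}

#' Write a score model as a coefficient table
#'
#' @param model a [score_model()].
#' @param path output path; the intercept is written as a `(Intercept)` row
#'   when non-zero.
#' @param digits significant digits (default 6).
#' @return `path`, invisibly.
#' @export
write_score_model <- function(model, path, digits = 6) {
  stopifnot(inherits(model, "score_model"))
  df <- data.frame(cpg_id = model$cpgs, weight = signif(model$weights, digits))
  if (model$intercept != 0)
    df <- rbind(data.frame(cpg_id = .INTERCEPT_ID,
                           weight = signif(model$intercept, digits)), df)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# serialization helpers shared by classifier JSON
.model_to_list <- function(m) {
  list(name = m$name, cpgs = m$cpgs, weights = m$weights,
       intercept = m$intercept)
}

.model_from_list <- function(l) {
  score_model(unlist(l$cpgs), unlist(l$weights),
              intercept = as.numeric(l$intercept), name = l$name)
}
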