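#' Construct a validated beta-value matrix
#'
#' A `beta_matrix` holds DNA-methylation beta values (methylation fractions)
#' as a numeric matrix with CpGs in rows and samples in columns. Values must
#' lie in \[0, 1\]; values straying outside by at most `tol` (floating-point
#' noise from upstream normalisation) are clamped, anything further out is
#' rejected. `NA` cells are permitted and recorded as missing; policy for
#' missing values is decided at scoring time (see [compute_score()]).
#'
#' @param values numeric matrix of methylation fractions, CpGs x samples.
#' @param cpg_ids character vector of unique CpG identifiers (row names).
#'   Taken from `rownames(values)` if omitted.
#' @param sample_ids character vector of unique sample identifiers (column
#'   names). Taken from `colnames(values)` if omitted.
#' @param tol numeric; values within `tol` outside \[0, 1\] are clamped.
#' @return an object of class `beta_matrix`: a numeric matrix with complete
#'   dimnames.
#' @examples
#' b <- beta_matrix(matrix(c(0.1, 0.9, 0.4, 0.6), 2,
#'                         dimnames = list(c("cg01", "cg02"), c("s1", "s2"))))
#' dim(b)
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values), tol = 1e-9) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("beta matrix is empty", call. = FALSE)
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("CpG and sample identifiers are required", call. = FALSE)
  cpg_ids <- as.character(cpg_ids)
  sample_ids <- as.character(sample_ids)
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cpg_ids))
    stop("duplicate CpG id: ", cpg_ids[duplicated(cpg_ids)][1L], call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L],
         call. = FALSE)
  if (!is.numeric(values))
    stop("beta values must be numeric", call. = FALSE)
  bad <- which(!is.na(values) & (values < -tol | values > 1 + tol))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "beta value %g out of [0,1] at CpG '%s' (row %d), sample '%s' (column %d)",
      values[bad[1L]], cpg_ids[i[1L]], i[1L], sample_ids[i[2L]], i[2L]),
      call. = FALSE)
  }
  nonfinite <- which(!is.na(values) & !is.finite(values))
  if (length(nonfinite)) {
    i <- arrayInd(nonfinite[1L], dim(values))
    stop(sprintf("non-finite beta value at row %d, column %d", i[1L], i[2L]),
         call. = FALSE)
  }
  values[!is.na(values) & values < 0] <- 0
  values[!is.na(values) & values > 1] <- 1
  dimnames(values) <- list(cpg_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples", nrow(x), ncol(x)))
  n_na <- sum(is.na(x))
  if (n_na > 0) cat(sprintf(" (%d missing cells)", n_na))
  cat("\n")
  rng <- range(x, na.rm = TRUE)
  cat(sprintf("  values in [%.4f, %.4f]\n", rng[1L], rng[2L]))
  invisible(x)
}

# shared delimiter detection: TSV unless the extension says CSV
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_delim_table <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = .delim_for(path), header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"", na.strings = c("NA", ""))
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV or CSV file (delimiter chosen by extension) laid out like a
#' GEO series-matrix table: one header row of sample ids and an id column of
#' CpG ids (`orientation = "cpg_rows"`, the default), or the transpose
#' (`orientation = "sample_rows"`).
#'
#' @param path file path.
#' @param orientation `"cpg_rows"` (CpGs in rows) or `"sample_rows"`.
#' @return a [beta_matrix()].
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, orientation = c("cpg_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  df <- .read_delim_table(path)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("beta matrix file must have an id column and at least one data column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  dat <- df[, -1L, drop = FALSE]
  for (j in seq_along(dat)) {
    col <- dat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                     col[bad[1L]], bad[1L], names(dat)[j], path), call. = FALSE)
      dat[[j]] <- num
    }
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  if (orientation == "sample_rows") m <- t(m)
  beta_matrix(m)
}

#' Write a beta-value matrix to delimited text
#'
#' @param beta a [beta_matrix()].
#' @param path output path; `.csv` writes comma-separated, anything else tabs.
#' @param orientation layout to write, as in [read_beta_matrix()].
#' @param digits significant digits for serialisation (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path,
                              orientation = c("cpg_rows", "sample_rows"),
                              digits = 6) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(beta, "beta_matrix"))
  m <- unclass(beta)
  id_col <- "cpg_id"
  if (orientation == "sample_rows") {
    m <- t(m)
    id_col <- "sample_id"
  }
  df <- data.frame(signif(m, digits), check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), id_col), df)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a sample sheet
#'
#' A sample sheet maps sample ids to self-reported smoking status
#' (`current`, `former` or `never`), with optional covariate columns
#' (age, sex, study) passed through untouched.
#'
#' @param path file path (TSV or CSV by extension).
#' @return `read_sample_sheet()` returns a data frame with at least columns
#'   `sample_id` and `status` (factor with levels current/former/never).
#' @export
read_sample_sheet <- function(path) {
  df <- .read_delim_table(path)
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a data frame with columns `sample_id` and `status`.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- sample_sheet(sheet)
  utils::write.table(sheet, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
smoking_levels <- c("current", "former", "never")

#' Validate a sample sheet
#'
#' @param sheet data frame with `sample_id` and `status` columns; `status`
#'   must only use the values current/former/never.
#' @return the validated sheet with `status` as a factor on those levels.
#' @export
sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "status") %in% names(sheet)))
    stop("sample sheet needs 'sample_id' and 'status' columns", call. = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample id: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1L], call. = FALSE)
  st <- as.character(sheet$status)
  bad <- setdiff(unique(st), smoking_levels)
  if (length(bad))
    stop("unknown smoking status value(s): ", paste(bad, collapse = ", "),
         "; expected current/former/never", call. = FALSE)
  sheet$status <- factor(st, levels = smoking_levels)
  sheet
}
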