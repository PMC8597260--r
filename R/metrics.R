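# --- confusion-matrix evaluation battery ----------------------------------

#' No-information rate
#'
#' The largest observed class proportion: the accuracy achieved by always
#' predicting the majority class.
#'
#' @param actual vector of observed class labels.
#' @return a fraction in (0, 1].
#' @export
nir <- function(actual) {
  actual <- as.character(actual)
  if (length(actual) == 0L) stop("empty label vector", call. = FALSE)
  if (anyNA(actual)) stop("labels contain NA", call. = FALSE)
  max(table(actual)) / length(actual)
}

#' Confusion-matrix summary: accuracy, NIR, kappa and per-class statistics
#'
#' Builds the predicted-by-actual confusion matrix and the evaluation battery
#' used for smoking-status classifiers: overall accuracy with an exact
#' (Clopper-Pearson) binomial 95% confidence interval; the no-information
#' rate with a one-sided exact binomial test of accuracy exceeding it;
#' unweighted Cohen's kappa; and one-vs-rest sensitivity, specificity,
#' positive and negative predictive value for every class.
#'
#' Kappa is `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' products of row and column marginals. In the fully degenerate case where
#' both sides contain a single identical class (`p_e = 1`), kappa is defined
#' as 0 with a warning.
#'
#' @param pred predicted class labels.
#' @param actual observed class labels (same length).
#' @param classes optional character vector fixing the class set and order;
#'   defaults to the sorted union of the observed vocabularies.
#' @return object of class `confusion_summary` with fields `matrix`
#'   (predicted rows x actual columns), `n`, `accuracy`, `accuracy_ci95`,
#'   `nir`, `p_acc_gt_nir`, `kappa`, and `per_class` (a data frame with one
#'   row per class).
#' @examples
#' cs <- confusion_summary(c("a", "a", "b"), c("a", "b", "b"))
#' cs$accuracy
#' @export
confusion_summary <- function(pred, actual, classes = NULL) {
  pred <- as.character(pred)
  actual <- as.character(actual)
  if (length(pred) != length(actual))
    stop("pred and actual differ in length", call. = FALSE)
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(pred) || anyNA(actual)) stop("labels contain NA", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(pred, actual)))
  bad <- setdiff(c(pred, actual), classes)
  if (length(bad))
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pred <- factor(pred, levels = classes)
  actual <- factor(actual, levels = classes)
  m <- table(predicted = pred, actual = actual)
  n <- length(pred)
  hits <- sum(diag(m))
  accuracy <- hits / n

  bt <- stats::binom.test(hits, n)
  ci <- as.numeric(bt$conf.int)

  nir_val <- max(colSums(m)) / n
  p_nir <- stats::binom.test(hits, n, p = nir_val,
                             alternative = "greater")$p.value

  p_o <- accuracy
  p_e <- sum((rowSums(m) / n) * (colSums(m) / n))
  if (p_e >= 1 - .Machine$double.eps^0.5) {
    warning("degenerate confusion matrix (expected agreement = 1); kappa set to 0",
            call. = FALSE)
    kappa <- 0
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }

  per_class <- do.call(rbind, lapply(classes, function(cls) {
    tp <- m[cls, cls]
    fp <- sum(m[cls, ]) - tp
    fn <- sum(m[, cls]) - tp
    tn <- n - tp - fp - fn
    data.frame(class = cls,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL

  structure(list(matrix = m, n = n, accuracy = accuracy,
                 accuracy_ci95 = ci, nir = nir_val, p_acc_gt_nir = p_nir,
                 kappa = kappa, per_class = per_class),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, digits = 4, ...) {
  cat("Confusion matrix (predicted rows x actual columns):\n")
  print(unclass(x$matrix))
  cat(sprintf("\nAccuracy: %.*f (95%% CI %.*f-%.*f)\n", digits, x$accuracy,
              digits, x$accuracy_ci95[1L], digits, x$accuracy_ci95[2L]))
  cat(sprintf("NIR: %.*f (P[Acc > NIR] = %.3g)\n", digits, x$nir,
              x$p_acc_gt_nir))
  cat(sprintf("Kappa: %.*f\n\n", digits, x$kappa))
  pc <- x$per_class
  pc[-1L] <- lapply(pc[-1L], round, digits)
  print(pc, row.names = FALSE)
  invisible(x)
}

.summary_to_list <- function(x) {
  list(classes = colnames(x$matrix),
       # predicted rows x actual columns, serialised as an array of rows
       matrix = matrix(as.integer(x$matrix), nrow = nrow(x$matrix)),
       n = x$n, accuracy = x$accuracy, accuracy_ci95 = x$accuracy_ci95,
       nir = x$nir, p_acc_gt_nir = x$p_acc_gt_nir, kappa = x$kappa,
       per_class = x$per_class)
}

#' Write an evaluation report (JSON + plain-text rendering)
#'
#' Writes the summary as JSON at `path` (full double precision, so a
#' round-trip through [read_report()] reproduces every field exactly) and a
#' human-readable rendering of the same numbers at `path` with a `.txt`
#' extension appended.
#'
#' @param summary a [confusion_summary()].
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path) {
  stopifnot(inherits(summary, "confusion_summary"))
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(.summary_to_list(summary), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(summary, digits = 6)), con)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("classes", "matrix", "n", "accuracy", "accuracy_ci95",
                "nir", "p_acc_gt_nir", "kappa", "per_class")
  absent <- setdiff(required, names(obj))
  if (length(absent))
    stop("report is missing field(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  m <- as.table(matrix(as.integer(obj$matrix), nrow = length(obj$classes),
                       dimnames = list(predicted = obj$classes,
                                       actual = obj$classes)))
  structure(list(matrix = m, n = as.integer(obj$n),
                 accuracy = as.numeric(obj$accuracy),
                 accuracy_ci95 = as.numeric(obj$accuracy_ci95),
                 nir = as.numeric(obj$nir),
                 p_acc_gt_nir = as.numeric(obj$p_acc_gt_nir),
                 kappa = as.numeric(obj$kappa),
                 per_class = as.data.frame(obj$per_class)),
            class = "confusion_summary")
}
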