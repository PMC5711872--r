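# Round half up to `digits` decimals (accuracies are reported to 2
# decimals with half-up rounding, not banker's rounding).
.round_half_up <- function(x, digits = 2L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Build a confusion matrix over a fixed class order
#'
#' @param truth,predicted Equal-length label vectors; every label must
#'   appear in `class_order`.
#' @param class_order Ordered class labels (default: ascending sorted
#'   distinct true labels). Rows are true classes, columns predictions.
#' @return `K x K` integer matrix of class `"vss_confusion"` with the
#'   class labels as dimnames.
#' @export
confusion_matrix <- function(truth, predicted,
                             class_order = sort(unique(truth))) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  co <- as.character(class_order)
  truth <- as.character(truth); predicted <- as.character(predicted)
  unk <- setdiff(unique(c(truth, predicted)), co)
  if (length(unk))
    stop("label(s) not in class_order: ", paste(unk, collapse = ", "))
  cm <- table(factor(truth, levels = co), factor(predicted, levels = co))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(truth = co, predicted = co)
  structure(cm, class = c("vss_confusion", class(cm)))
}

.as_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || !length(cm))
    stop("confusion matrix must be square and non-empty")
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  cm
}

#' Score-tolerance accuracy of a confusion matrix
#'
#' Counts a prediction as correct when it lies within `tol` of the true
#' class. With the default `mode = "position"` the distance is measured
#' in positions within the ordered class list (`tol = 1` accepts the
#' adjacent observed classes); with `mode = "score"` it is the absolute
#' difference of the numeric class labels themselves. `tol = 0` is exact
#' accuracy in both modes. Returned as a percentage rounded half-up to 2
#' decimals.
#'
#' @param cm Square confusion matrix (rows true, columns predicted) with
#'   classes ordered ascending; see [confusion_matrix()].
#' @param tol Non-negative integer tolerance.
#' @param mode `"position"` (default) or `"score"` (requires numeric
#'   dimnames).
#' @return Percentage in `[0, 100]`, rounded to 2 decimals.
#' @export
tolerance_accuracy <- function(cm, tol, mode = c("position", "score")) {
  mode <- match.arg(mode)
  cm <- .as_confusion(cm)
  if (tol < 0) stop("tol must be non-negative")
  K <- nrow(cm)
  if (mode == "position") {
    d <- abs(outer(seq_len(K), seq_len(K), "-"))
  } else {
    lab <- suppressWarnings(as.numeric(rownames(cm)))
    if (anyNA(lab))
      stop("mode = 'score' needs numeric class labels as dimnames")
    d <- abs(outer(lab, lab, "-"))
  }
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  .round_half_up(100 * sum(cm[d <= tol]) / total, 2L)
}

#' Accuracy and per-class report for a confusion matrix
#'
#' Bundles the exact, one-score-tolerance and two-score-tolerance
#' accuracies (position mode, see [tolerance_accuracy()]) with per-class
#' recall and the labeled matrix.
#'
#' @param cm Square confusion matrix, classes ordered ascending.
#' @param mode Tolerance mode, as in [tolerance_accuracy()].
#' @return Object of class `"vss_report"`: list with `accuracy`
#'   (named vector `exact`, `tol1`, `tol2`), `recall`, `n` and
#'   `confusion`.
#' @export
evaluation_report <- function(cm, mode = c("position", "score")) {
  mode <- match.arg(mode)
  cm <- .as_confusion(cm)
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(recall) <- rownames(cm)
  structure(list(
    accuracy = c(exact = tolerance_accuracy(cm, 0L, mode),
                 tol1 = tolerance_accuracy(cm, 1L, mode),
                 tol2 = tolerance_accuracy(cm, 2L, mode)),
    recall = recall, n = sum(cm), confusion = cm, mode = mode),
    class = "vss_report")
}

#' @export
print.vss_report <- function(x, ...) {
  cat("VSS rating evaluation (n = ", x$n, ", ", x$mode,
      " tolerance)\n", sep = "")
  cat(sprintf("  exact: %.2f%%   one-score: %.2f%%   two-score: %.2f%%\n",
              x$accuracy["exact"], x$accuracy["tol1"],
              x$accuracy["tol2"]))
  cat("  confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x$confusion))
  cat("  per-class recall:\n")
  print(round(x$recall, 3))
  invisible(x)
}

#' Serialize / restore an evaluation report as JSON
#'
#' @param x A `"vss_report"`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "vss_report"))
  obj <- list(n = x$n, mode = x$mode,
              accuracy = as.list(x$accuracy),
              recall = as.list(x$recall),
              class_order = rownames(x$confusion),
              confusion = unclass(x$confusion))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname report_to_json
#' @param json JSON string or file path produced by [report_to_json()].
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cm <- matrix(as.numeric(obj$confusion), nrow = length(obj$class_order),
               dimnames = list(truth = obj$class_order,
                               predicted = obj$class_order))
  rep <- evaluation_report(cm, mode = obj$mode)
  rep
}

#' Packaged reference confusion matrices
#'
#' Two 8-class leave-one-out confusion matrices from the original
#' clinical evaluation of this pipeline on 216 scar sub-images (classes
#' = observed VSS totals 0, 1, 2, 4, 5, 7, 8, 9), shipped as plain-CSV
#' fixtures: `"osvm"` for the ECOC classifier with the optimized SVM
#' learner on the LBP + SV texture and full color feature combination,
#' and `"knn"` for the ECOC 1-nearest-neighbor run on LBP + SV + GLCM
#' plus full color. They serve as worked examples for
#' [tolerance_accuracy()] and [evaluation_report()].
#'
#' @param which `"osvm"` or `"knn"`.
#' @return `8 x 8` integer matrix with VSS-total dimnames.
#' @export
reference_confusion <- function(which = c("osvm", "knn")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("confusion_ecoc_", which, ".csv"),
                   package = "scarvss", mustWork = TRUE)
  read_confusion_csv(f)
}

#' Read / write a labeled confusion-matrix CSV grid
#'
#' The format is a square grid with the class labels as both the header
#' row and the first column.
#'
#' @param path CSV path.
#' @return Integer matrix with class-label dimnames.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  cm <- as.matrix(df)
  if (nrow(cm) != ncol(cm))
    stop("malformed confusion-matrix CSV (not square): ", path)
  if (anyNA(cm)) stop("malformed confusion-matrix CSV (missing values): ",
                      path)
  dimnames(cm) <- list(truth = rownames(df), predicted = colnames(df))
  cm
}

#' @rdname read_confusion_csv
#' @param cm Square labeled matrix.
#' @export
write_confusion_csv <- function(cm, path) {
  cm <- .as_confusion(cm)
  df <- as.data.frame(unclass(cm))
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
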