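# High-level pipeline runners: each wraps the module functions so a
# whole stage (synthesis, feature extraction, cross-validation,
# matrix evaluation) is one call. The command-line dispatcher in
# inst/cli/scarvss.R is a thin wrapper over these.

#' Write a synthetic study dataset to disk
#'
#' Generates the synthetic study dataset ([generate_study_dataset()])
#' and writes the 24 parent images as PNG files plus a `manifest.csv`
#' readable by [load_manifest()].
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param separation,size Passed to the generator.
#' @return Path of the written manifest, invisibly.
#' @export
run_synth <- function(out_dir, seed = 1L, separation = 1,
                      size = c(99L, 99L)) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  ds <- generate_study_dataset(seed,
                               default_class_specs(separation),
                               size)
  for (i in seq_along(ds$images)) {
    f <- file.path(out_dir, paste0(ds$manifest$image_id[i], ".png"))
    png::writePNG(ds$images[[i]] / 255, f)
    ds$manifest$path[i] <- f
  }
  write_manifest(ds$manifest, file.path(out_dir, "manifest.csv"))
}

#' Extract a feature table for every sub-image of a manifest
#'
#' Loads each manifest image, applies the 3x3 sub-image expansion and
#' extracts the requested feature combination. When `out_file` is given
#' the table is written as CSV (`sample_id`, `label`, then the named
#' feature columns).
#'
#' @param manifest Manifest CSV path or a data.frame from
#'   [load_manifest()].
#' @param combo Feature combination (see [parse_combo()]).
#' @param out_file Optional output CSV path.
#' @param ... Extraction options forwarded to [extract_features()].
#' @return The `"scar_features"` object, invisibly when written.
#' @export
run_features <- function(manifest, combo = "(LBP+SV)+(RGB+HSV+Lab)",
                         out_file = NULL, ...) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  images <- lapply(manifest$path, load_image)
  sub <- expand_subimages(list(images = images, manifest = manifest))
  fm <- extract_features(sub$samples, combo, labels = sub$labels,
                         sample_ids = sub$sample_ids, ...)
  if (!is.null(out_file)) {
    df <- data.frame(sample_id = fm$sample_ids, label = fm$labels,
                     fm$values, check.names = FALSE)
    utils::write.csv(df, out_file, row.names = FALSE)
    return(invisible(fm))
  }
  fm
}

#' Read a feature table written by [run_features()]
#'
#' @param path Feature CSV path.
#' @return A `"scar_features"` object (unstandardized, single unnamed
#'   block spanning all columns).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("feature table must have sample_id and label columns: ", path)
  vals <- as.matrix(df[setdiff(names(df), c("sample_id", "label"))])
  rownames(vals) <- df$sample_id
  structure(list(values = vals, sample_ids = df$sample_id,
                 labels = df$label,
                 blocks = list(ALL = seq_len(ncol(vals))),
                 combo = "ALL", standardized = FALSE, center = NULL,
                 scale = NULL, frozen = NULL),
            class = "scar_features")
}

#' Standardize, leave-one-out cross-validate and report
#'
#' Standardizes the feature matrix dataset-wide (the protocol fidelity
#' default; see the methods vignette for the leakage caveat), runs
#' [loo_cross_validate()] and summarizes with [evaluation_report()].
#' When `out_dir` is given, writes `report.json`, `report.txt`,
#' `confusion.csv` and `predictions.csv`.
#'
#' @param fm A `"scar_features"` object or a feature-table CSV path.
#' @param learner,decoding,seed As in [loo_cross_validate()].
#' @param tolerance_mode `"position"` or `"score"` (see
#'   [tolerance_accuracy()]).
#' @param out_dir Optional output directory.
#' @return The `"vss_report"`, with the `"loo_result"` attached as
#'   attribute `"loo"`.
#' @export
run_loo <- function(fm, learner = "knn1", decoding = NULL, seed = 1L,
                    tolerance_mode = c("position", "score"),
                    out_dir = NULL) {
  tolerance_mode <- match.arg(tolerance_mode)
  if (is.character(fm)) fm <- read_feature_table(fm)
  if (!fm$standardized) fm <- standardize(fm)
  loo <- loo_cross_validate(fm, learner = learner, decoding = decoding,
                            seed = seed)
  cm <- confusion_matrix(loo$truth, loo$predicted,
                         sort(unique(as.numeric(loo$truth))))
  rep <- evaluation_report(cm, mode = tolerance_mode)
  attr(rep, "loo") <- loo
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)
    report_to_json(rep, file.path(out_dir, "report.json"))
    utils::capture.output(print(rep),
                          file = file.path(out_dir, "report.txt"))
    write_confusion_csv(cm, file.path(out_dir, "confusion.csv"))
    utils::write.csv(data.frame(sample_id = loo$sample_ids,
                                true_label = loo$truth,
                                predicted_label = loo$predicted),
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  rep
}

#' Evaluate a stored confusion-matrix CSV
#'
#' Reads a labeled confusion-matrix grid (see [read_confusion_csv()])
#' and reports its exact / one-score / two-score tolerance accuracies.
#'
#' @param path Confusion-matrix CSV path.
#' @param tolerance_mode As in [tolerance_accuracy()].
#' @return A `"vss_report"`.
#' @export
run_eval_matrix <- function(path, tolerance_mode = c("position",
                                                     "score")) {
  evaluation_report(read_confusion_csv(path),
                    mode = match.arg(tolerance_mode))
}
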