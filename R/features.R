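# Canonical block order; every feature matrix lists its blocks (and hence
# its columns) in this order restricted to the requested combination.
.block_order <- c("GLCM", "SV", "LBP", "RGB", "HSV", "LAB")

#' Parse a feature-combination name
#'
#' Combination names use the `+`/parenthesis notation, e.g.
#' `"(LBP+SV)+(RGB+HSV+Lab)"` or `"GLCM"`. Tokens (case-insensitive):
#' `GLCM`, `SV`, `LBP`, `RGB`, `HSV`, `Lab`. Parentheses and whitespace
#' are cosmetic; duplicates collapse; the result is always in the
#' canonical block order GLCM, SV, LBP, RGB, HSV, LAB.
#'
#' @param combo Combination string, or a character vector of tokens.
#' @return Character vector of canonical block names.
#' @export
parse_combo <- function(combo) {
  if (!length(combo)) stop("empty feature combination")
  tokens <- toupper(unlist(strsplit(gsub("[()[:space:]]", "",
                                         paste(combo, collapse = "+")),
                                    "+", fixed = TRUE)))
  tokens <- tokens[nzchar(tokens)]
  bad <- setdiff(tokens, .block_order)
  if (length(bad))
    stop("unknown feature block(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(.block_order, collapse = ", "), ")")
  if (!length(tokens)) stop("empty feature combination")
  .block_order[.block_order %in% tokens]
}

.block_fun <- function(block, rgb, gray, glcm_levels, glcm_offset,
                       sv_lags, lbp_cfg, hist_bins) {
  switch(block,
    GLCM = glcm_features(compute_glcm(quantize(gray, glcm_levels),
                                      glcm_offset, glcm_levels)),
    SV   = sv_features(gray, sv_lags),
    LBP  = lbp_histogram(gray, lbp_cfg),
    RGB  = rgb_moments(rgb),
    HSV  = hsv_histogram_features(rgb, hist_bins),
    LAB  = lab_histogram_features(rgb, hist_bins))
}

#' Extract a named feature matrix from a set of image samples
#'
#' Computes the requested feature blocks for every sample: texture blocks
#' (GLCM 19 features, semi-variogram 20, LBP-code histogram 256) on the
#' grayscale conversion, color blocks (RGB moments 12, HSV histograms 12,
#' CIELAB histograms 12) on the RGB pixels. Columns are concatenated in
#' the canonical order GLCM, SV, LBP, RGB, HSV, LAB restricted to the
#' combination.
#'
#' @param samples List of `H x W x 3` RGB arrays (values 0--255).
#' @param combo Feature combination (see [parse_combo()]); default all
#'   six blocks.
#' @param labels Optional VSS total score per sample.
#' @param sample_ids Optional sample identifiers; default `s0001, ...`.
#' @param glcm_levels,glcm_offset Gray-level count and offset for the
#'   co-occurrence block (defaults: 8 levels, one pixel to the right).
#' @param sv_lags Semi-variogram lags per direction (default 10).
#' @param lbp_cfg An [lbp_config()] (default 8 neighbors, radius 1).
#' @param hist_bins Bins per color-histogram channel (default 4).
#' @return Object of class `"scar_features"`: list with `values`
#'   (samples x features numeric matrix with named columns),
#'   `sample_ids`, `labels`, `blocks` (name -> column indices),
#'   `combo`, and standardization state (`standardized`, `center`,
#'   `scale`, `frozen`).
#' @export
extract_features <- function(samples, combo = .block_order, labels = NULL,
                             sample_ids = NULL, glcm_levels = 8L,
                             glcm_offset = c(0L, 1L), sv_lags = 10L,
                             lbp_cfg = lbp_config(), hist_bins = 4L) {
  blocks <- parse_combo(combo)
  if (!length(samples)) stop("no samples")
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%04d", seq_along(samples))
  if (!is.null(labels) && length(labels) != length(samples))
    stop("labels and samples differ in length")
  rows <- lapply(samples, function(rgb) {
    gray <- to_grayscale(rgb)
    unlist(lapply(blocks, .block_fun, rgb = rgb, gray = gray,
                  glcm_levels = glcm_levels, glcm_offset = glcm_offset,
                  sv_lags = sv_lags, lbp_cfg = lbp_cfg,
                  hist_bins = hist_bins))
  })
  values <- do.call(rbind, rows)
  rownames(values) <- sample_ids
  sizes <- vapply(blocks, function(b)
    length(.block_fun(b, samples[[1L]], to_grayscale(samples[[1L]]),
                      glcm_levels, glcm_offset, sv_lags, lbp_cfg,
                      hist_bins)), integer(1))
  ends <- cumsum(sizes)
  idx <- Map(function(e, s) (e - s + 1L):e, ends, sizes)
  names(idx) <- blocks
  structure(list(values = values, sample_ids = sample_ids,
                 labels = labels, blocks = idx,
                 combo = paste(blocks, collapse = "+"),
                 standardized = FALSE, center = NULL, scale = NULL,
                 frozen = NULL),
            class = "scar_features")
}

#' @export
print.scar_features <- function(x, ...) {
  cat("Scar feature matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " features [", x$combo, "]",
      if (x$standardized) ", standardized", "\n", sep = "")
  invisible(x)
}

#' Standardize a feature matrix to zero mean and unit variance
#'
#' Column-wise z-scores using the sample (N-1) standard deviation,
#' computed over the whole dataset. Zero-variance columns are set to
#' all-zero and flagged as frozen (not dropped, so column counts stay
#' stable across combinations). The column means and standard deviations
#' are stored so held-out samples can be transformed consistently; pass
#' a previously standardized feature matrix as `stats` to reuse its
#' statistics.
#'
#' @param fm A `"scar_features"` object with at least 2 samples.
#' @param stats Optional standardized `"scar_features"` whose stored
#'   `center`/`scale` are applied instead of recomputing.
#' @return The standardized `"scar_features"` object.
#' @export
standardize <- function(fm, stats = NULL) {
  stopifnot(inherits(fm, "scar_features"))
  if (is.null(stats)) {
    if (fm$standardized) stop("feature matrix is already standardized")
    if (nrow(fm$values) < 2L)
      stop("standardization needs at least 2 samples")
    ctr <- colMeans(fm$values)
    scl <- apply(fm$values, 2L, stats::sd)
    frozen <- !is.finite(scl) | scl <= 0
    scl[frozen] <- 1
  } else {
    stopifnot(inherits(stats, "scar_features"), stats$standardized)
    ctr <- stats$center; scl <- stats$scale; frozen <- stats$frozen
  }
  z <- sweep(sweep(fm$values, 2L, ctr, "-"), 2L, scl, "/")
  z[, frozen] <- 0
  fm$values <- z
  fm$standardized <- TRUE
  fm$center <- ctr; fm$scale <- scl; fm$frozen <- frozen
  fm
}
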