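# VSS subscale upper bounds (pigmentation, vascularity, pliability,
# height); the total therefore ranges over 0..13.
.vss_limits <- c(pigmentation = 2L, vascularity = 3L, pliability = 5L,
                 height = 3L)

.manifest_cols <- c("image_id", "path", "pigmentation", "vascularity",
                    "pliability", "height", "patient_id", "site")

#' Read and validate a scar image manifest
#'
#' The manifest is a UTF-8 CSV with mandatory header columns
#' `image_id,path,pigmentation,vascularity,pliability,height,patient_id,site`.
#' Each row describes one cropped scar image and its Vancouver Scar Scale
#' subscores: pigmentation 0--2, vascularity 0--3, pliability 0--5,
#' height 0--3. The VSS total (0--13) is always recomputed as the sum of
#' the four subscores; a `vss_total` column, if present, is cross-checked
#' against that sum and a mismatch is an error. Unknown extra columns are
#' ignored with a warning.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with the eight manifest columns plus the derived
#'   `vss_total`, one row per image.
#' @seealso [write_manifest()], [generate_study_dataset()]
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.manifest_cols, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(.manifest_cols, "vss_total"))
  if (length(extra))
    warning("ignoring unknown manifest column(s): ",
            paste(extra, collapse = ", "))
  stored_total <- if ("vss_total" %in% names(df)) df$vss_total else NULL
  df <- df[.manifest_cols]
  for (sc in names(.vss_limits)) {
    v <- suppressWarnings(as.integer(df[[sc]]))
    bad <- which(is.na(v) | v < 0L | v > .vss_limits[[sc]])
    if (length(bad))
      stop("manifest row ", bad[1L], " (image_id '", df$image_id[bad[1L]],
           "'): ", sc, " score '", df[[sc]][bad[1L]],
           "' outside [0, ", .vss_limits[[sc]], "]")
    df[[sc]] <- v
  }
  dup <- df$image_id[duplicated(df$image_id)]
  if (length(dup))
    stop("duplicate image_id in manifest: ", dup[1L])
  df$vss_total <- df$pigmentation + df$vascularity + df$pliability +
    df$height
  if (!is.null(stored_total)) {
    st <- suppressWarnings(as.integer(stored_total))
    bad <- which(!is.na(st) & st != df$vss_total)
    if (length(bad))
      stop("manifest row ", bad[1L], " (image_id '", df$image_id[bad[1L]],
           "'): stored vss_total ", st[bad[1L]],
           " does not equal the subscore sum ", df$vss_total[bad[1L]])
  }
  df
}

#' Write a scar image manifest
#'
#' Writes records in the CSV layout read by [load_manifest()], including
#' the derived `vss_total` column.
#'
#' @param records Data.frame with the manifest columns (as returned by
#'   [load_manifest()] or [generate_study_dataset()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  missing <- setdiff(.manifest_cols, names(records))
  if (length(missing))
    stop("records are missing column(s): ", paste(missing, collapse = ", "))
  records$vss_total <- records$pigmentation + records$vascularity +
    records$pliability + records$height
  utils::write.csv(records[c(.manifest_cols, "vss_total")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
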