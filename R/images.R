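#' Read a scar photograph as an 8-bit RGB array
#'
#' Decodes a PNG, JPEG or TIFF file into an `H x W x 3` integer array with
#' values in 0--255. Grayscale sources are replicated across the three
#' channels; an alpha channel, if present, is dropped. 16-bit sources are
#' rescaled to 8 bits by integer division of the full range
#' (`value %/% 257`, so 65535 maps to 255).
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff` file.
#' @return Integer array of dimension `H x W x 3`, values in `[0, 255]`,
#'   with `H >= 3` and `W >= 3`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(c(1, 0, 0), c(9, 9, 3)), f)  # all-red
#' img <- load_image(f)
#' stopifnot(all(img[, , 1] == 255), all(img[, , 2:3] == 0))
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image, file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = tiff::readTIFF(path, as.is = TRUE),
      stop("unsupported image format '", ext, "' for: ", path)
    ),
    error = function(e) stop("failed to decode image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  px <- .to_rgb255(raw)
  .validate_rgb(px, path)
  px
}

# Normalize decoder output (normalized doubles or raw integers, 1-4
# channels) to an H x W x 3 integer array in 0..255.
.to_rgb255 <- function(raw) {
  if (is.double(raw) && length(raw) && max(raw) <= 1) {
    # png/jpeg return values scaled to [0,1] by (2^depth - 1)
    v16 <- round(raw * 65535)
    is8 <- all(abs(raw * 255 - round(raw * 255)) < 1e-9)
    px <- if (is8) round(raw * 255) else v16 %/% 257
  } else {
    # tiff as.is = TRUE: raw integers at native depth
    px <- if (max(raw) > 255) raw %/% 257 else raw
  }
  px <- pmin(pmax(px, 0), 255)
  d <- dim(px)
  if (is.null(d) || length(d) == 2L)
    px <- array(px, c(dim(as.matrix(px)), 1L))
  nc <- dim(px)[3L]
  if (nc == 1L || nc == 2L) {
    px <- array(px[, , 1L], c(dim(px)[1:2], 3L))     # gray (+alpha)
  } else if (nc == 4L) {
    px <- px[, , 1:3, drop = FALSE]                   # drop alpha
  }
  storage.mode(px) <- "integer"
  px
}

.validate_rgb <- function(px, what = "image") {
  d <- dim(px)
  if (length(d) != 3L || d[3L] != 3L)
    stop("not an RGB image (need H x W x 3): ", what)
  if (d[1L] < 3L || d[2L] < 3L)
    stop("image too small (need at least 3 x 3 pixels): ", what)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("pixel values out of the 8-bit range [0, 255]: ", what)
  invisible(px)
}

#' Convert an RGB array to 8-bit grayscale luma
#'
#' Per pixel, `gray = round(0.2989 R + 0.5870 G + 0.1140 B)` (ITU-R BT.601
#' weights, rounding half away from zero), clipped to `[0, 255]`.
#' Achromatic pixels (`R = G = B = c`) map to `c` exactly.
#'
#' @param img `H x W x 3` array with values in 0--255 (see [load_image()]).
#' @return Integer matrix `H x W`, values in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  .validate_rgb(img)
  g <- 0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
  g <- floor(g + 0.5)             # inputs are non-negative
  g <- pmin(pmax(g, 0), 255)
  storage.mode(g) <- "integer"
  g
}

#' Divide an image into an equal-size grid of sub-images
#'
#' Splits an image into `rows x cols` tiles of size
#' `floor(H/rows) x floor(W/cols)`, returned in row-major order (left to
#' right, then top to bottom). Trailing remainder rows/columns at the
#' bottom and right are discarded so every tile has identical shape. This
#' is the 3x3 sub-image expansion used to turn each cropped scar
#' photograph into 9 classification samples.
#'
#' @param img An `H x W x 3` RGB array or an `H x W` grayscale matrix.
#' @param rows,cols Grid dimensions; defaults 3 x 3.
#' @return List of `rows * cols` tiles with the same number of channels as
#'   the input.
#' @export
subdivide <- function(img, rows = 3L, cols = 3L) {
  d <- dim(img)
  is_rgb <- length(d) == 3L
  H <- d[1L]; W <- d[2L]
  if (rows < 1L || cols < 1L) stop("rows and cols must be positive")
  if (H < rows || W < cols)
    stop("image (", H, " x ", W, ") smaller than the ", rows, " x ", cols,
         " subdivision grid")
  th <- H %/% rows; tw <- W %/% cols
  tiles <- vector("list", rows * cols)
  k <- 0L
  for (i in seq_len(rows)) {
    ri <- ((i - 1L) * th + 1L):(i * th)
    for (j in seq_len(cols)) {
      ci <- ((j - 1L) * tw + 1L):(j * tw)
      k <- k + 1L
      tiles[[k]] <- if (is_rgb) img[ri, ci, , drop = FALSE]
                    else        img[ri, ci, drop = FALSE]
    }
  }
  tiles
}
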