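#' Directional image semi-variogram
#'
#' The semi-variogram at lag `h` is half the mean squared intensity
#' difference over all pixel pairs separated by exactly `h` pixels along
#' one axis: `gamma(h) = sum_i (f(x_i) - f(x_i + h))^2 / (2 m(h))`, with
#' `m(h)` the number of such pairs. It summarizes the global spatial
#' correlation structure of the image: smooth fields rise slowly with
#' lag, rough fields jump immediately. Computed on the unquantized
#' grayscale intensities (isotropy is assumed; only the two axis-aligned
#' directions are offered).
#'
#' @param img Numeric matrix of intensities.
#' @param n_lags Number of lags (default 10); the image extent along the
#'   chosen direction must exceed `n_lags`.
#' @param direction `"horizontal"` (lag along columns) or `"vertical"`
#'   (lag along rows).
#' @return Object of class `"semivariogram"`: list with `lags` (1..n_lags),
#'   `gamma` (squared-intensity units), `m` (pair counts) and `direction`.
#' @examples
#' ramp <- matrix(rep(0:31, each = 32), 32)  # f(row, col) = col - 1
#' semivariogram(ramp, direction = "horizontal")$gamma[1:2]  # 0.5, 2
#' @export
semivariogram <- function(img, n_lags = 10L,
                          direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (!is.matrix(img)) stop("img must be a matrix")
  if (n_lags < 1L) stop("n_lags must be positive")
  if (direction == "vertical") img <- t(img)
  W <- ncol(img)
  if (W <= n_lags)
    stop("image extent (", W, ") along the ", direction,
         " direction must exceed n_lags (", n_lags, ")")
  img <- img * 1.0
  gamma <- numeric(n_lags); m <- integer(n_lags)
  for (h in seq_len(n_lags)) {
    d <- img[, seq_len(W - h), drop = FALSE] -
         img[, (h + 1L):W, drop = FALSE]
    m[h] <- length(d)
    gamma[h] <- sum(d^2) / (2 * m[h])
  }
  structure(list(lags = seq_len(n_lags), gamma = gamma, m = m,
                 direction = direction),
            class = "semivariogram")
}

#' @export
print.semivariogram <- function(x, ...) {
  cat("Semi-variogram (", x$direction, "), ", length(x$lags), " lags\n",
      sep = "")
  print(stats::setNames(x$gamma, paste0("h=", x$lags)))
  invisible(x)
}

#' 20-value semi-variogram feature block
#'
#' Concatenates the horizontal profile `gamma(1..n_lags)` followed by the
#' vertical profile, computed on the unquantized grayscale image.
#'
#' @param img Numeric matrix of intensities, at least
#'   `(n_lags + 1) x (n_lags + 1)`.
#' @param n_lags Lags per direction (default 10).
#' @return Named numeric vector `sv_h_1 ... sv_h_10, sv_v_1 ... sv_v_10`.
#' @export
sv_features <- function(img, n_lags = 10L) {
  h <- semivariogram(img, n_lags, "horizontal")$gamma
  v <- semivariogram(img, n_lags, "vertical")$gamma
  stats::setNames(c(h, v),
                  c(paste0("sv_h_", seq_len(n_lags)),
                    paste0("sv_v_", seq_len(n_lags))))
}
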