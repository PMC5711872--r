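#' First four central moments of a channel
#'
#' Population (divide-by-N) central moments: mean, variance `m2`,
#' skewness `m3 / m2^(3/2)` and non-excess kurtosis `m4 / m2^2` (a
#' Gaussian sample tends to 3). A constant channel returns
#' `(c, 0, 0, 0)` by convention.
#'
#' @param values Numeric vector of channel samples (at least one).
#' @return Named numeric vector `mean, var, skew, kurt`.
#' @export
channel_moments <- function(values) {
  if (!length(values)) stop("channel_moments: empty input")
  values <- as.numeric(values)
  m1 <- mean(values)
  d <- values - m1
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  c(mean = m1, var = m2, skew = skew, kurt = kurt)
}

#' RGB central-moment feature block (12 values)
#'
#' Four central moments per channel, in channel order R, G, B.
#'
#' @param img `H x W x 3` RGB array, values 0--255.
#' @return Named numeric vector `rgb_r_mean ... rgb_b_kurt`.
#' @export
rgb_moments <- function(img) {
  .validate_rgb(img)
  out <- c(channel_moments(img[, , 1L]), channel_moments(img[, , 2L]),
           channel_moments(img[, , 3L]))
  names(out) <- paste0("rgb_", rep(c("r", "g", "b"), each = 4L), "_",
                       rep(c("mean", "var", "skew", "kurt"), 3L))
  out
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone conversion via [grDevices::rgb2hsv()]; hue is scaled
#' to `[0, 1]` (degrees / 360), saturation and value are in `[0, 1]`.
#'
#' @param img `H x W x 3` RGB array, values 0--255.
#' @return `H x W x 3` double array of H, S, V planes.
#' @export
rgb_to_hsv <- function(img) {
  .validate_rgb(img)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1L]),
                                  as.vector(img[, , 2L]),
                                  as.vector(img[, , 3L])),
                            maxColorValue = 255)
  array(t(hsv), c(dim(img)[1:2], 3L))
}

#' Convert an RGB image to CIELAB
#'
#' Assumes the pixels are sRGB under the D65 illuminant (no camera
#' calibration data are available): gamma expansion to linear RGB, then
#' XYZ, then CIELAB, via [grDevices::convertColor()]. `L*` spans 0
#' (black) to 100 (diffuse white); `a*` and `b*` are the green--magenta
#' and blue--yellow opponent axes, near 0 for achromatic pixels.
#'
#' @param img `H x W x 3` RGB array, values 0--255.
#' @return `H x W x 3` double array of L*, a*, b* planes.
#' @export
rgb_to_lab <- function(img) {
  .validate_rgb(img)
  srgb <- cbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
                as.vector(img[, , 3L])) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  array(lab, c(dim(img)[1:2], 3L))
}

#' Fixed-range 4-bin normalized histogram
#'
#' Equal-width bins over the nominal range `[lo, hi]` (not data-driven,
#' so features are comparable across images); values outside the range
#' are clipped into it; the last bin is right-closed, so a value exactly
#' at `hi` falls in the final bin. Normalized to sum 1.
#'
#' @param values Numeric samples (at least one).
#' @param range Numeric pair `(lo, hi)` with `hi > lo`.
#' @param bins Number of bins (default 4).
#' @return Numeric vector of `bins` relative frequencies.
#' @export
histogram4 <- function(values, range, bins = 4L) {
  if (!length(values)) stop("histogram4: empty input")
  lo <- range[1L]; hi <- range[2L]
  if (!(hi > lo)) stop("histogram4: range must satisfy hi > lo")
  x <- pmin(pmax(as.numeric(values), lo), hi)
  idx <- floor((x - lo) / (hi - lo) * bins) + 1L
  idx[idx > bins] <- bins
  h <- tabulate(idx, nbins = bins)
  h / sum(h)
}

.hist_block <- function(planes, channels, ranges, prefix, bins = 4L) {
  out <- numeric(0)
  for (k in seq_along(channels)) {
    h <- histogram4(planes[, , k], ranges[[k]], bins)
    names(h) <- paste0(prefix, "_", channels[k], "_bin", seq_len(bins))
    out <- c(out, h)
  }
  out
}

#' HSV histogram feature block (12 values)
#'
#' 4-bin normalized histograms of the H, S and V planes, each over the
#' nominal range `[0, 1]`. Hue is binned linearly (no circular
#' wrap-around), a deliberate simplification.
#'
#' @param img `H x W x 3` RGB array, values 0--255.
#' @param bins Bins per channel (default 4).
#' @return Named numeric vector `hsv_h_bin1 ... hsv_v_bin4`.
#' @export
hsv_histogram_features <- function(img, bins = 4L) {
  .hist_block(rgb_to_hsv(img), c("h", "s", "v"),
              list(c(0, 1), c(0, 1), c(0, 1)), "hsv", bins)
}

#' CIELAB histogram feature block (12 values)
#'
#' 4-bin normalized histograms of L* over `[0, 100]` and of a*, b* over
#' `[-128, 127]` (values clipped into these nominal ranges).
#'
#' @param img `H x W x 3` RGB array, values 0--255.
#' @param bins Bins per channel (default 4).
#' @return Named numeric vector `lab_l_bin1 ... lab_b_bin4`.
#' @export
lab_histogram_features <- function(img, bins = 4L) {
  .hist_block(rgb_to_lab(img), c("l", "a", "b"),
              list(c(0, 100), c(-128, 127), c(-128, 127)), "lab", bins)
}
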