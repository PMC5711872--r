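#' Local binary pattern configuration
#'
#' @param neighbors Number of circularly sampled neighbors `V` (default 8).
#' @param radius Sampling circle radius `R` in pixels (default 1).
#' @param rotation_invariant Map each code to the minimum over its bit
#'   rotations? Default `FALSE` (the raw-code convention, keeping the
#'   full `2^V`-bin histogram).
#' @return Object of class `"lbp_config"`.
#' @export
lbp_config <- function(neighbors = 8L, radius = 1,
                       rotation_invariant = FALSE) {
  if (neighbors < 2L) stop("neighbors must be at least 2")
  if (radius <= 0) stop("radius must be positive")
  structure(list(neighbors = as.integer(neighbors), radius = radius,
                 rotation_invariant = isTRUE(rotation_invariant),
                 interpolation = "bilinear"),
            class = "lbp_config")
}

# Neighbor v = 0 sits due east at offset (0, +R); subsequent neighbors
# proceed counter-clockwise at angles 2*pi*v/V. Offsets within 1e-9 of an
# integer are snapped so cardinal neighbors need no interpolation.
.lbp_offsets <- function(cfg) {
  v <- seq_len(cfg$neighbors) - 1L
  ang <- 2 * pi * v / cfg$neighbors
  dr <- -cfg$radius * sin(ang)
  dc <- cfg$radius * cos(ang)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  cbind(dr = snap(dr), dc = snap(dc))
}

.lbp_rotmin <- function(codes, V) {
  best <- codes
  cur <- codes
  top <- bitwShiftL(1L, V - 1L)
  for (s in seq_len(V - 1L)) {
    carry <- bitwAnd(cur, 1L)
    cur <- bitwShiftR(cur, 1L) + carry * top
    best <- pmin(best, cur)
  }
  best
}

#' Local binary pattern code of one pixel
#'
#' Samples `V` neighbors on the circle of radius `R` around pixel `u`
#' (neighbor 0 due east, counter-clockwise), bilinearly interpolating at
#' non-integer positions, and sets bit `v` when the neighbor is at least
#' as bright as the center (`f_v - f_u >= 0`, so a constant patch yields
#' the all-ones code `2^V - 1`).
#'
#' @param img Numeric matrix of intensities.
#' @param u Integer pair `(row, col)`, 1-based; must lie at least `R`
#'   pixels from every border.
#' @param cfg An [lbp_config()].
#' @return Integer code in `[0, 2^V - 1]`.
#' @export
lbp_code <- function(img, u, cfg = lbp_config()) {
  if (!is.matrix(img)) stop("img must be a matrix")
  r <- u[1L]; c <- u[2L]
  R <- cfg$radius
  if (r - R < 1 || r + R > nrow(img) || c - R < 1 || c + R > ncol(img))
    stop("pixel (", r, ", ", c, ") is closer than radius ", R,
         " to the image border")
  off <- .lbp_offsets(cfg)
  center <- img[r, c]
  code <- 0L
  for (v in seq_len(cfg$neighbors)) {
    fv <- .bilinear(img, r + off[v, 1L], c + off[v, 2L])
    if (fv - center >= 0) code <- code + bitwShiftL(1L, v - 1L)
  }
  if (cfg$rotation_invariant) code <- .lbp_rotmin(code, cfg$neighbors)
  code
}

.bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  wr <- r - r0; wc <- c - c0
  r1 <- min(r0 + 1, nrow(img)); c1 <- min(c0 + 1, ncol(img))
  (1 - wr) * (1 - wc) * img[r0, c0] + (1 - wr) * wc * img[r0, c1] +
    wr * (1 - wc) * img[r1, c0] + wr * wc * img[r1, c1]
}

#' Normalized histogram of local binary pattern codes
#'
#' Computes [lbp_code()] at every interior pixel (those at least `R` from
#' the border) and returns the `2^V`-bin relative-frequency histogram,
#' normalized to sum 1.
#'
#' @inheritParams lbp_code
#' @return Named numeric vector of length `2^V`
#'   (`lbp_000 ... lbp_255` for the default `V = 8`).
#' @export
lbp_histogram <- function(img, cfg = lbp_config()) {
  if (!is.matrix(img)) stop("img must be a matrix")
  R <- cfg$radius
  rlo <- ceiling(1 + R); rhi <- floor(nrow(img) - R)
  clo <- ceiling(1 + R); chi <- floor(ncol(img) - R)
  if (rlo > rhi || clo > chi)
    stop("image too small for LBP radius ", R,
         " (need at least (2R+1) x (2R+1) pixels)")
  rows <- rlo:rhi; cols <- clo:chi
  center <- img[rows, cols, drop = FALSE]
  off <- .lbp_offsets(cfg)
  codes <- matrix(0L, length(rows), length(cols))
  for (v in seq_len(cfg$neighbors)) {
    dr <- off[v, 1L]; dc <- off[v, 2L]
    r0 <- floor(dr); c0 <- floor(dc)
    wr <- dr - r0; wc <- dc - c0
    sub <- function(a, b) img[rows + a, cols + b, drop = FALSE]
    fv <- (1 - wr) * (1 - wc) * sub(r0, c0) +
          (1 - wr) * wc       * sub(r0, c0 + 1 * (wc > 0)) +
          wr * (1 - wc)       * sub(r0 + 1 * (wr > 0), c0) +
          wr * wc             * sub(r0 + 1 * (wr > 0), c0 + 1 * (wc > 0))
    codes <- codes + bitwShiftL(1L, v - 1L) * (fv - center >= 0)
  }
  if (cfg$rotation_invariant) codes <- .lbp_rotmin(codes, cfg$neighbors)
  nb <- 2L^cfg$neighbors
  h <- tabulate(codes + 1L, nbins = nb)
  h <- h / sum(h)
  stats::setNames(h, sprintf("lbp_%03d", 0:(nb - 1L)))
}
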