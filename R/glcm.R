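#' Quantize a grayscale image to a small number of gray levels
#'
#' Equal-width binning over the observed intensity range
#' `[min(img), max(img)]`: the minimum maps to level 1, the maximum to
#' level `num_levels`, and a constant image maps entirely to level 1.
#' Co-occurrence statistics are computed on this quantized image.
#'
#' @param img Numeric matrix of intensities.
#' @param num_levels Number of gray levels (default 8; must be >= 2).
#' @return Integer matrix with values in `1..num_levels`.
#' @export
quantize <- function(img, num_levels = 8L) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (num_levels < 2L) stop("num_levels must be at least 2")
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    q <- matrix(1L, nrow(img), ncol(img))
    return(q)
  }
  q <- floor((img - lo) / (hi - lo) * num_levels) + 1L
  q[q > num_levels] <- num_levels        # the maximum lands in the top bin
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix for one pixel offset
#'
#' Counts ordered pixel pairs `(u, v = u + offset)` whose quantized values
#' are `(p, q)`, for a single (non-symmetric) offset, and normalizes the
#' counts by the total number of co-occurring pairs `n(h)` to obtain the
#' co-occurrence probabilities. The default offset `(0, 1)` pairs each
#' pixel with its right-hand neighbor.
#'
#' @param img Integer matrix with values in `1..num_levels` (see
#'   [quantize()]).
#' @param offset Integer pair `(drow, dcol)`.
#' @param num_levels Number of gray levels `L`; defaults to `max(img)`.
#' @return Object of class `"glcm"`: list with `counts` and `probs`
#'   (`L x L` matrices), `offset`, `num_levels` and `n_pairs`.
#' @examples
#' g <- compute_glcm(matrix(1:4, 2, byrow = TRUE), offset = c(0, 1))
#' g$n_pairs  # 2 pairs: (1,2) and (3,4)
#' @export
compute_glcm <- function(img, offset = c(0L, 1L), num_levels = max(img)) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (length(offset) != 2L || any(offset != round(offset)))
    stop("offset must be an integer (drow, dcol) pair")
  if (min(img) < 1L || max(img) > num_levels)
    stop("img must hold quantized levels in 1..num_levels")
  H <- nrow(img); W <- ncol(img)
  dr <- as.integer(offset[1L]); dc <- as.integer(offset[2L])
  ri <- seq_len(H); ci <- seq_len(W)
  ri <- ri[ri + dr >= 1L & ri + dr <= H]
  ci <- ci[ci + dc >= 1L & ci + dc <= W]
  if (!length(ri) || !length(ci))
    stop("empty GLCM: no pixel pairs exist for offset (", dr, ", ", dc, ")")
  p <- img[ri, ci, drop = FALSE]
  q <- img[ri + dr, ci + dc, drop = FALSE]
  L <- as.integer(num_levels)
  counts <- matrix(tabulate((p - 1L) * L + q, nbins = L * L),
                   L, L, byrow = TRUE)
  n <- sum(counts)
  structure(list(counts = counts, probs = counts / n,
                 offset = c(dr, dc), num_levels = L, n_pairs = n),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat("Gray-level co-occurrence matrix: ", x$num_levels, " levels, offset (",
      x$offset[1L], ", ", x$offset[2L], "), ", x$n_pairs, " pairs\n",
      sep = "")
  invisible(x)
}

# 0 * log(0) == 0 convention used by all entropy terms.
.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 19 co-occurrence texture features
#'
#' Computes, from the co-occurrence probabilities `p(i, j)` of a single
#' offset, the fixed 19-feature vector used for scar texture description:
#' entropy, energy, correlation, contrast, sum of squares (variance), sum
#' average, sum variance, sum entropy, difference variance, difference
#' entropy, the first information measure of correlation, autocorrelation,
#' dissimilarity, homogeneity, cluster prominence, cluster shade, maximum
#' probability, inverse difference normalized and inverse difference
#' moment normalized. All entropies use natural logarithms with the
#' `0 log 0 = 0` convention; degenerate denominators (zero marginal
#' standard deviation, zero marginal entropy) yield 0. Sum variance is
#' centered on the sum average, the standard correction of the original
#' formulation. The second information measure of correlation is appended
#' when `extras = TRUE` but is not part of the canonical 19.
#'
#' @param g A `"glcm"` object from [compute_glcm()].
#' @param extras Append `glcm_imc2`? Default `FALSE`.
#' @return Named numeric vector of length 19 (20 with `extras`), names
#'   `glcm_entropy ... glcm_idmn`.
#' @export
glcm_features <- function(g, extras = FALSE) {
  stopifnot(inherits(g, "glcm"))
  if (g$n_pairs <= 0) stop("GLCM has no pairs")
  P <- g$probs
  L <- g$num_levels
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sdx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(L) - muy)^2 * py))

  # distributions of i + j (support 2..2L) and |i - j| (support 0..L-1)
  psum <- vapply(2:(2L * L), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2L * L)
  pdif <- vapply(0:(L - 1L), function(k) sum(P[abs(i - j) == k]),
                 numeric(1))
  kd <- 0:(L - 1L)

  entropy <- -sum(.xlogx(P))
  energy <- sum(P^2)
  correlation <- if (sdx * sdy > 0)
    sum((i - mux) * (j - muy) * P) / (sdx * sdy) else 0
  contrast <- sum((i - j)^2 * P)
  variance <- sum((i - mux)^2 * P)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(.xlogx(psum))
  dmean <- sum(kd * pdif)
  diff_variance <- sum((kd - dmean)^2 * pdif)
  diff_entropy <- -sum(.xlogx(pdif))
  hx <- -sum(.xlogx(px)); hy <- -sum(.xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxy > 0, P * log(pxy), 0))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  autocorrelation <- sum(i * j * P)
  dissimilarity <- sum(abs(i - j) * P)
  homogeneity <- sum(P / (1 + abs(i - j)))
  cluster_prominence <- sum((i + j - mux - muy)^4 * P)
  cluster_shade <- sum((i + j - mux - muy)^3 * P)
  max_prob <- max(P)
  idn <- sum(P / (1 + abs(i - j) / L))
  idmn <- sum(P / (1 + (i - j)^2 / L^2))

  out <- c(glcm_entropy = entropy, glcm_energy = energy,
           glcm_correlation = correlation, glcm_contrast = contrast,
           glcm_variance = variance, glcm_sum_average = sum_average,
           glcm_sum_variance = sum_variance, glcm_sum_entropy = sum_entropy,
           glcm_diff_variance = diff_variance,
           glcm_diff_entropy = diff_entropy, glcm_imc1 = imc1,
           glcm_autocorrelation = autocorrelation,
           glcm_dissimilarity = dissimilarity,
           glcm_homogeneity = homogeneity,
           glcm_cluster_prominence = cluster_prominence,
           glcm_cluster_shade = cluster_shade,
           glcm_max_prob = max_prob, glcm_idn = idn, glcm_idmn = idmn)
  if (extras) {
    hxy2 <- -sum(.xlogx(pxy))
    arg <- 1 - exp(-2 * (hxy2 - entropy))
    out <- c(out, glcm_imc2 = sqrt(max(arg, 0)))
  }
  out
}
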