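# Independent naive reimplementations used as oracles. These are written
# directly from the defining formulas with explicit loops and stay
# deliberately separate from the package internals they check.

random_gray <- function(seed, H = 8L, W = 8L, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, H * W, replace = TRUE), H, W)
}

random_rgb <- function(seed, H = 9L, W = 9L) {
  set.seed(seed)
  a <- array(sample(0:255, H * W * 3L, replace = TRUE), c(H, W, 3L))
  storage.mode(a) <- "integer"
  a
}

# -- GLCM oracle -------------------------------------------------------

oracle_glcm_counts <- function(img, offset, L) {
  cnt <- matrix(0L, L, L)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img))
      cnt[img[r, c], img[r2, c2]] <- cnt[img[r, c], img[r2, c2]] + 1L
  }
  cnt
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  xlx <- function(p) if (p > 0) p * log(p) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sdx <- sqrt(sum(((1:L) - mux)^2 * px))
  sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  ent <- 0; ene <- 0; corr <- 0; con <- 0; varr <- 0; ac <- 0; dis <- 0
  hom <- 0; cp <- 0; cs <- 0; idn <- 0; idmn <- 0; hxy1 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    ent <- ent - xlx(p)
    ene <- ene + p^2
    con <- con + (i - j)^2 * p
    varr <- varr + (i - mux)^2 * p
    ac <- ac + i * j * p
    dis <- dis + abs(i - j) * p
    hom <- hom + p / (1 + abs(i - j))
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    idn <- idn + p / (1 + abs(i - j) / L)
    idmn <- idmn + p / (1 + (i - j)^2 / L^2)
    if (sdx * sdy > 0) corr <- corr + (i - mux) * (j - muy) * p /
        (sdx * sdy)
    if (p > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - p * log(px[i] * py[j])
  }
  psum <- sapply(2:(2 * L), function(k) {
    s <- 0
    for (i in 1:L) for (j in 1:L) if (i + j == k) s <- s + P[i, j]
    s
  })
  pdif <- sapply(0:(L - 1), function(k) {
    s <- 0
    for (i in 1:L) for (j in 1:L) if (abs(i - j) == k) s <- s + P[i, j]
    s
  })
  sa <- sum((2:(2 * L)) * psum)
  sv <- sum(((2:(2 * L)) - sa)^2 * psum)
  se <- -sum(sapply(psum, xlx))
  dmean <- sum((0:(L - 1)) * pdif)
  dv <- sum(((0:(L - 1)) - dmean)^2 * pdif)
  de <- -sum(sapply(pdif, xlx))
  hx <- -sum(sapply(px, xlx)); hy <- -sum(sapply(py, xlx))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  c(ent, ene, corr, con, varr, sa, sv, se, dv, de, imc1, ac, dis, hom,
    cp, cs, max(P), idn, idmn)
}

# -- semi-variogram oracle --------------------------------------------

oracle_semivariogram <- function(img, h, direction) {
  tot <- 0; m <- 0L
  H <- nrow(img); W <- ncol(img)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (direction == "horizontal" && c + h <= W) {
      tot <- tot + (img[r, c] - img[r, c + h])^2
      m <- m + 1L
    }
    if (direction == "vertical" && r + h <= H) {
      tot <- tot + (img[r, c] - img[r + h, c])^2
      m <- m + 1L
    }
  }
  tot / (2 * m)
}

# -- LBP oracle --------------------------------------------------------

oracle_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  dr <- r - r0; dc <- c - c0
  r1 <- min(r0 + 1, nrow(img)); c1 <- min(c0 + 1, ncol(img))
  (1 - dr) * (1 - dc) * img[r0, c0] + (1 - dr) * dc * img[r0, c1] +
    dr * (1 - dc) * img[r1, c0] + dr * dc * img[r1, c1]
}

oracle_lbp_code <- function(img, r, c, V = 8L, R = 1) {
  code <- 0
  for (v in 0:(V - 1)) {
    ang <- 2 * pi * v / V
    rr <- r - R * sin(ang); cc <- c + R * cos(ang)
    if (abs(rr - round(rr)) < 1e-9) rr <- round(rr)
    if (abs(cc - round(cc)) < 1e-9) cc <- round(cc)
    fv <- oracle_bilinear(img, rr, cc)
    if (fv - img[r, c] >= 0) code <- code + 2^v
  }
  code
}

# -- colorimetry oracle (scalar sRGB -> CIELAB, D65) -------------------

oracle_srgb_to_lab <- function(rgb255) {
  lin <- sapply(rgb255 / 255, function(u)
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)          # D65
  f <- sapply(xyz / wp, function(t)
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

# -- pairwise majority vote oracle for one-vs-one decoding -------------

# votes: named +/-1 per column "i_vs_j" (vote +1 means class i wins).
# Ties in total wins resolve to the smallest class label.
oracle_pairwise_majority <- function(votes, coding) {
  cls <- rownames(coding)
  wins <- setNames(numeric(length(cls)), cls)
  for (b in seq_len(ncol(coding))) {
    pos <- cls[coding[, b] == 1]; neg <- cls[coding[, b] == -1]
    if (votes[b] > 0) wins[pos] <- wins[pos] + 1
    else if (votes[b] < 0) wins[neg] <- wins[neg] + 1
    else { wins[pos] <- wins[pos] + 0.5; wins[neg] <- wins[neg] + 0.5 }
  }
  cls[which.max(wins)]
}

# -- misc --------------------------------------------------------------

constant_rgb <- function(r, g, b, H = 9L, W = 9L) {
  a <- array(0L, c(H, W, 3L))
  a[, , 1] <- as.integer(r); a[, , 2] <- as.integer(g)
  a[, , 3] <- as.integer(b)
  a
}

# well-separated two-cloud dataset for classifier tests
two_clouds <- function(seed, n = 20L, gap = 8, p = 5L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, gap), n))
  list(x = x, y = rep(c(1L, 3L), each = n))
}
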