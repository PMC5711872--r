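# Observed VSS totals in the study design and the number of cropped
# parent images per total; subdividing 3x3 yields 216 samples with
# per-class counts 27, 81, 18, 9, 9, 45, 9, 18.
.study_labels <- c(0L, 1L, 2L, 4L, 5L, 7L, 8L, 9L)
.study_counts <- c(3L, 9L, 2L, 1L, 1L, 5L, 1L, 2L)

# Fixed per-label decomposition into the four VSS subscales
# (pigmentation 0-2, vascularity 0-3, pliability 0-5, height 0-3).
.study_subscores <- matrix(
  c(0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L,
    1L, 1L, 0L, 0L,
    1L, 1L, 1L, 1L,
    2L, 1L, 1L, 1L,
    2L, 2L, 2L, 1L,
    2L, 2L, 2L, 2L,
    2L, 3L, 2L, 2L),
  ncol = 4L, byrow = TRUE,
  dimnames = list(as.character(.study_labels),
                  c("pigmentation", "vascularity", "pliability",
                    "height")))

#' Default synthetic class specifications
#'
#' One specification per observed VSS total. Class difficulty is
#' controlled by two orthogonal knobs: the mean color (`base_rgb`, spaced
#' across color space) and the spatial correlation length of the texture
#' (`texture_scale`, the smoothing radius in pixels), so color-only and
#' texture-only feature combinations are each informative in isolation.
#' `separation` scales every knob toward its across-class center: 1 is
#' the well-separated default, 0 collapses all classes onto one
#' indistinguishable spec.
#'
#' Two properties of the default table matter. First, smoothing scales
#' stay small (0--4 pixels): a sum-one box kernel of radius `s` leaves
#' only about `(33 / (2 s + 1))^2` independent texture patches in a
#' 33 x 33 tile, so large scales would make per-tile texture estimates
#' (LBP histograms, semi-variograms) unstable and smear the class
#' clusters. Second, no two classes share the same
#' (scale, contrast-to-noise) pair — local binary patterns are invariant
#' to overall contrast, so they can only tell classes apart through that
#' pair — while the absolute `noise_sd` and `amplitude` levels separate
#' classes in the semi-variogram sill/nugget and color-variance
#' features, and the mean colors are spread widely across RGB space.
#'
#' @param separation Between-class separation factor in `[0, 1]`.
#' @return Named list of per-class specs (label, base_rgb,
#'   texture_scale, noise_sd, amplitude).
#' @export
default_class_specs <- function(separation = 1) {
  base_colors <- rbind(
    c(225, 190, 170),   # 0: near-normal pale skin
    c(200, 110, 100),   # 1: light pink
    c(215, 150, 205),   # 2: pink-violet
    c(140, 200, 140),   # 4: green-tinged
    c(100, 110, 215),   # 5: blue-violet
    c(185, 50, 50),     # 7: deep red
    c(120, 70, 30),     # 8: dark brown
    c(60, 40, 110))     # 9: dark purple
  scales <- c(0, 2, 4, 1, 3, 0, 2, 4)
  noises <- c(2, 4, 3, 10, 8, 14, 7, 18)
  amps <- c(60, 110, 100, 70, 110, 25, 40, 140)
  toward <- function(x, w) mean(x) + w * (x - mean(x))
  specs <- lapply(seq_along(.study_labels), function(k) {
    list(label = .study_labels[k],
         base_rgb = colMeans(base_colors) +
           separation * (base_colors[k, ] - colMeans(base_colors)),
         texture_scale = toward(scales, separation)[k],
         noise_sd = toward(noises, separation)[k],
         amplitude = toward(amps, separation)[k])
  })
  names(specs) <- as.character(.study_labels)
  specs
}

# Normalized box blur of radius r with replicated edges (separable,
# cumulative-sum implementation).
.box_smooth <- function(m, radius) {
  r <- as.integer(round(radius))
  if (r <= 0L) return(m)
  smooth1 <- function(x) {
    # x: matrix, smooth along rows (i.e. down columns)
    n <- nrow(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x,
                x[rep(n, r), , drop = FALSE])
    cs <- apply(xp, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(2L * r + 2L):(n + 2L * r + 1L), , drop = FALSE] -
       cs[1L:n, , drop = FALSE]) / (2L * r + 1L)
  }
  t(smooth1(t(smooth1(m))))
}

#' Generate one synthetic class-structured scar image
#'
#' Produces a colored texture field emulating a scar patch of one class:
#' a constant base color plus `amplitude` times a smoothed white-noise
#' field (one field shared across the three channels, smoothed by a
#' normalized box kernel of radius `texture_scale`, which sets the
#' spatial correlation length) plus independent per-channel white noise
#' of standard deviation `noise_sd`. Pixels are rounded and clipped to
#' `[0, 255]`. Deterministic given `seed`.
#'
#' @param spec A class spec (see [default_class_specs()]).
#' @param size Integer `(H, W)`, each at least 33 so that 3x3 tiles still
#'   support 10-lag semi-variograms.
#' @param seed Integer seed.
#' @return `H x W x 3` integer RGB array.
#' @export
generate_class_image <- function(spec, size = c(99L, 99L), seed = 1L) {
  H <- size[1L]; W <- size[2L]
  if (length(size) != 2L || H < 33L || W < 33L)
    stop("size must be (H, W) with both at least 33")
  .with_seed(seed, {
    field <- .box_smooth(matrix(stats::rnorm(H * W), H, W),
                         spec$texture_scale)
    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) {
      plane <- spec$base_rgb[ch] + spec$amplitude * field +
        stats::rnorm(H * W, sd = spec$noise_sd)
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    storage.mode(img) <- "integer"
    img
  })
}

#' Generate the synthetic study dataset
#'
#' Emulates the study design with no clinical images: 24 parent images
#' whose class labels are the observed VSS totals `{0, 1, 2, 4, 5, 7, 8,
#' 9}` with per-class parent counts `3, 9, 2, 1, 1, 5, 1, 2`; dividing
#' each parent 3x3 with [subdivide()] yields the 216 labeled sub-image
#' samples (27, 81, 18, 9, 9, 45, 9, 18 per class). Manifest rows carry
#' a fixed VSS subscore decomposition summing to each label. All
#' randomness flows through one generator seeded per call.
#'
#' @param seed Integer seed.
#' @param specs Per-class specs (default [default_class_specs()]).
#' @param size Parent image size `(H, W)`, default `c(99, 99)`.
#' @return List with `images` (24 RGB arrays, in manifest order) and
#'   `manifest` (data.frame in the [load_manifest()] layout, `path`
#'   empty).
#' @export
generate_study_dataset <- function(seed = 1L,
                                   specs = default_class_specs(),
                                   size = c(99L, 99L)) {
  n_parent <- sum(.study_counts)
  sub_seeds <- .with_seed(seed,
                          sample.int(.Machine$integer.max, n_parent))
  images <- vector("list", n_parent)
  rows <- vector("list", n_parent)
  sites <- c("abdomen", "wrist", "elbow", "chest", "shoulder", "neck",
             "back", "flank", "lower arm", "upper arm", "axilla",
             "buttock")
  k <- 0L
  for (ci in seq_along(.study_labels)) {
    lab <- .study_labels[ci]
    for (r in seq_len(.study_counts[ci])) {
      k <- k + 1L
      images[[k]] <- generate_class_image(specs[[as.character(lab)]],
                                          size, sub_seeds[k])
      ss <- .study_subscores[as.character(lab), ]
      rows[[k]] <- data.frame(
        image_id = sprintf("vss%d_img%02d", lab, r),
        path = "",
        pigmentation = ss[["pigmentation"]],
        vascularity = ss[["vascularity"]],
        pliability = ss[["pliability"]],
        height = ss[["height"]],
        patient_id = sprintf("P%02d", k),
        site = sites[(k - 1L) %% length(sites) + 1L],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$vss_total <- manifest$pigmentation + manifest$vascularity +
    manifest$pliability + manifest$height
  list(images = images, manifest = manifest)
}

#' Expand parent images into labeled sub-image samples
#'
#' Applies the 3x3 [subdivide()] expansion to every parent image and
#' replicates its manifest label to the 9 tiles, in row-major tile
#' order.
#'
#' @param dataset A list as returned by [generate_study_dataset()], or
#'   separate `images`/`manifest` arguments.
#' @param rows,cols Subdivision grid (default 3 x 3).
#' @return List with `samples` (list of RGB tiles), `labels` (VSS totals)
#'   and `sample_ids` (`<image_id>_t<tile>`).
#' @export
expand_subimages <- function(dataset, rows = 3L, cols = 3L) {
  images <- dataset$images; manifest <- dataset$manifest
  n <- length(images)
  stopifnot(n == nrow(manifest))
  per <- rows * cols
  samples <- vector("list", n * per)
  labels <- integer(n * per)
  ids <- character(n * per)
  for (i in seq_len(n)) {
    tiles <- subdivide(images[[i]], rows, cols)
    at <- ((i - 1L) * per + 1L):(i * per)
    samples[at] <- tiles
    labels[at] <- manifest$vss_total[i]
    ids[at] <- sprintf("%s_t%d", manifest$image_id[i], seq_len(per))
  }
  list(samples = samples, labels = labels, sample_ids = ids)
}
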