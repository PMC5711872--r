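test_that("channel moments match direct computation", {
  expect_equal(channel_moments(rep(80, 10)), c(80, 0, 0, 0),
               ignore_attr = TRUE)
  # two-point symmetric sample: variance N-normalized, kurtosis 1
  m <- channel_moments(c(0, 0, 255, 255))
  expect_equal(unname(m), c(127.5, 16256.25, 0, 1))
  # any symmetric sample has zero skewness
  expect_equal(unname(channel_moments(c(-3, -1, 0, 1, 3) + 10)[3]), 0,
               tolerance = 1e-12)
  expect_error(channel_moments(numeric(0)), "empty")
})

test_that("moments are invariant to pixel order", {
  set.seed(42)
  v <- sample(0:255, 100, replace = TRUE)
  expect_equal(channel_moments(v), channel_moments(rev(sort(v))))
})

test_that("rgb_moments lays out R, G, B blocks in order", {
  expect_equal(unname(rgb_moments(constant_rgb(0, 0, 0))), rep(0, 12))
  f <- rgb_moments(constant_rgb(255, 0, 0))
  expect_equal(unname(f), c(255, 0, 0, 0, rep(0, 8)))
  expect_equal(names(f)[1:4],
               c("rgb_r_mean", "rgb_r_var", "rgb_r_skew", "rgb_r_kurt"))
  # half-black/half-white: each channel mean 127.5, kurtosis 1
  img <- constant_rgb(0, 0, 0, 10, 10)
  img[, 6:10, ] <- 255L
  f2 <- rgb_moments(img)
  expect_equal(unname(f2[c(1, 5, 9)]), rep(127.5, 3))
  expect_equal(unname(f2[c(4, 8, 12)]), rep(1, 3))
})

test_that("HSV conversion matches the hexcone landmarks", {
  expect_equal(rgb_to_hsv(constant_rgb(255, 0, 0))[1, 1, ], c(0, 1, 1))
  expect_equal(rgb_to_hsv(constant_rgb(0, 255, 0))[1, 1, ],
               c(1 / 3, 1, 1))
  expect_equal(rgb_to_hsv(constant_rgb(128, 128, 128))[1, 1, ],
               c(0, 0, 128 / 255))
})

test_that("HSV -> RGB round trip recovers 8-bit colors within one count", {
  set.seed(7)
  cols <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  err <- vapply(seq_len(nrow(cols)), function(i) {
    px <- constant_rgb(cols[i, 1], cols[i, 2], cols[i, 3], 3, 3)
    h <- rgb_to_hsv(px)[1, 1, ]
    back <- grDevices::col2rgb(grDevices::hsv(h[1], h[2], h[3]))[, 1]
    max(abs(back - cols[i, ]))
  }, numeric(1))
  expect_lte(max(err), 1)
})

test_that("CIELAB conversion matches the colorimetry oracle", {
  expect_equal(rgb_to_lab(constant_rgb(0, 0, 0))[1, 1, ], c(0, 0, 0),
               tolerance = 1e-6)
  w <- rgb_to_lab(constant_rgb(255, 255, 255))[1, 1, ]
  expect_equal(w[1], 100, tolerance = 1e-4)
  expect_lt(max(abs(w[2:3])), 1e-4)
  g <- rgb_to_lab(constant_rgb(119, 119, 119))[1, 1, ]
  expect_equal(unname(g), unname(oracle_srgb_to_lab(c(119, 119, 119))),
               tolerance = 0.1)
  # random colors against the scalar oracle
  set.seed(3)
  for (i in 1:25) {
    rgb <- sample(0:255, 3, replace = TRUE)
    expect_equal(unname(rgb_to_lab(constant_rgb(rgb[1], rgb[2],
                                                rgb[3]))[1, 1, ]),
                 unname(oracle_srgb_to_lab(rgb)), tolerance = 0.1)
  }
})

test_that("achromatic pixels have near-zero a* and b*", {
  for (v in c(10, 80, 160, 240)) {
    lab <- rgb_to_lab(constant_rgb(v, v, v))[1, 1, ]
    expect_lt(abs(lab[2]), 0.5)
    expect_lt(abs(lab[3]), 0.5)
  }
})

test_that("fixed-range histograms respect edge and closure rules", {
  expect_equal(histogram4(rep(0, 5), c(0, 1)), c(1, 0, 0, 0))
  expect_equal(histogram4(c(0.1, 0.3, 0.6, 0.9), c(0, 1)),
               rep(0.25, 4))
  expect_equal(histogram4(1, c(0, 1)), c(0, 0, 0, 1))   # hi in last bin
  expect_equal(histogram4(c(-5, 300), c(0, 255)), c(0.5, 0, 0, 0.5))
  expect_error(histogram4(numeric(0), c(0, 1)), "empty")
  expect_error(histogram4(1, c(1, 1)), "range")
})

test_that("HSV and Lab histogram blocks are normalized per channel", {
  f <- hsv_histogram_features(constant_rgb(255, 0, 0))
  expect_equal(unname(f), c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1))
  lb <- lab_histogram_features(constant_rgb(0, 0, 0))
  expect_equal(unname(lb[1:4]), c(1, 0, 0, 0))
  img <- random_rgb(21)
  for (blk in list(hsv_histogram_features(img),
                   lab_histogram_features(img))) {
    expect_length(blk, 12L)
    expect_true(all(blk >= 0))
    expect_equal(unname(blk[1:4] %*% rep(1, 4))[1], 1)
    expect_equal(sum(blk[5:8]), 1)
    expect_equal(sum(blk[9:12]), 1)
  }
})
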