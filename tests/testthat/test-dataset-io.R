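test_that("PNG round trip preserves 8-bit RGB pixels", {
  img <- random_rgb(11)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img / 255, f)
  expect_identical(load_image(f), img)
})

test_that("constant red PNG loads as pure red", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(rep(c(1, 0, 0), each = 81), c(9, 9, 3)), f)
  img <- load_image(f)
  expect_true(all(img[, , 1] == 255L))
  expect_true(all(img[, , 2:3] == 0L))
})

test_that("grayscale and alpha sources are normalized to 3 channels", {
  f <- withr::local_tempfile(fileext = ".png")
  g <- matrix(seq(0, 1, length.out = 25), 5)
  png::writePNG(g, f)
  img <- load_image(f)
  expect_equal(dim(img), c(5L, 5L, 3L))
  expect_identical(img[, , 1], img[, , 3])

  f4 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(stats::runif(100), c(5, 5, 4)), f4)
  expect_equal(dim(load_image(f4))[3], 3L)
})

test_that("16-bit TIFF is rescaled by integer division of the range", {
  f <- withr::local_tempfile(fileext = ".tif")
  v <- matrix(c(0L, 257L, 400L, 65535L, rep(1000L, 21)), 5, 5)
  tiff::writeTIFF(v / 65535, f, bits.per.sample = 16L)
  img <- load_image(f)
  expect_equal(img[1:4, 1, 1], c(0L, 257L, 400L, 65535L) %/% 257L)
})

test_that("unreadable and undersized images are rejected", {
  f <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", f)
  expect_error(load_image(f), "decode")
  expect_error(load_image(tempfile(fileext = ".png")), "not found")
  tiny <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 2, 2), tiny)
  expect_error(load_image(tiny), "too small")
})

test_that("grayscale conversion follows the luma weights", {
  expect_true(all(to_grayscale(constant_rgb(77, 77, 77)) == 77L))
  expect_true(all(to_grayscale(constant_rgb(255, 0, 0)) == 76L))
  expect_true(all(to_grayscale(constant_rgb(255, 255, 255)) == 255L))
  # idempotent on achromatic images: gray equals the channel value
  for (v in c(0L, 1L, 128L, 254L))
    expect_true(all(to_grayscale(constant_rgb(v, v, v)) == v))
})

test_that("subdivision tiles are equal-sized, row-major, and lossless", {
  img <- random_rgb(5, 9, 9)
  tiles <- subdivide(img)
  expect_length(tiles, 9L)
  expect_true(all(vapply(tiles, function(t) all(dim(t) == c(3, 3, 3)),
                         logical(1))))
  # reassembly reproduces the original when dimensions divide exactly
  rebuilt <- img
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    rebuilt[(i - 1) * 3 + 1:3, (j - 1) * 3 + 1:3, ] <- tiles[[k]]
  }
  expect_identical(rebuilt, img)
  # row-major order: tile 2 is the top-middle block
  expect_identical(tiles[[2]], img[1:3, 4:6, , drop = FALSE])
})

test_that("subdivision drops trailing remainder rows and columns", {
  img <- random_rgb(6, 10, 11)
  tiles <- subdivide(img)
  expect_length(tiles, 9L)
  expect_true(all(vapply(tiles, function(t) all(dim(t) == c(3, 3, 3)),
                         logical(1))))
  expect_identical(tiles[[9]], img[7:9, 7:9, , drop = FALSE])
  expect_error(subdivide(random_rgb(1, 3, 3), rows = 4), "smaller")
})

test_that("24 parent images yield 216 sub-images", {
  ds <- generate_study_dataset(seed = 3)
  expect_length(ds$images, 24L)
  expect_length(unlist(lapply(ds$images, subdivide), recursive = FALSE),
                216L)
})

test_that("manifest validation enforces VSS subscale ranges and totals", {
  rec <- data.frame(image_id = c("a", "b"), path = "",
                    pigmentation = c(2L, 0L), vascularity = c(3L, 0L),
                    pliability = c(5L, 0L), height = c(3L, 0L),
                    patient_id = "P1", site = "arm")
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(rec, f)
  m <- load_manifest(f)
  expect_equal(m$vss_total, c(13L, 0L))   # max total and normal skin

  bad <- rec; bad$pliability[1] <- 6L
  write_manifest2 <- function(df, p) utils::write.csv(df, p,
                                                      row.names = FALSE)
  write_manifest2(bad, f)
  expect_error(load_manifest(f), "pliability")

  dup <- rec; dup$image_id <- c("a", "a")
  write_manifest2(dup, f)
  expect_error(load_manifest(f), "duplicate")

  mis <- rec; mis$vss_total <- c(12L, 0L)
  write_manifest2(mis, f)
  expect_error(load_manifest(f), "vss_total")

  nocol <- rec[setdiff(names(rec), "site")]
  write_manifest2(nocol, f)
  expect_error(load_manifest(f), "site")

  extra <- rec; extra$note <- "x"
  write_manifest2(extra, f)
  expect_warning(load_manifest(f), "unknown")
})

test_that("manifest round trip preserves every field", {
  ds <- generate_study_dataset(seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(ds$manifest, f)
  m <- load_manifest(f)
  for (col in c("image_id", "pigmentation", "vascularity", "pliability",
                "height", "patient_id", "site", "vss_total"))
    expect_equal(m[[col]], ds$manifest[[col]], ignore_attr = TRUE)
})
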