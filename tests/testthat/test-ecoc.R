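test_that("one-vs-one coding enumerates class pairs", {
  expect_equal(ncol(build_ovo_coding(c(1, 2))), 1L)
  M3 <- build_ovo_coding(c(3, 1, 2, 1))
  expect_equal(colnames(M3), c("1_vs_2", "1_vs_3", "2_vs_3"))
  M8 <- build_ovo_coding(c(0, 1, 2, 4, 5, 7, 8, 9))
  expect_equal(ncol(M8), 28L)
  # every column: one +1, one -1, K-2 zeros; no duplicated columns
  expect_true(all(colSums(M8 == 1) == 1))
  expect_true(all(colSums(M8 == -1) == 1))
  expect_true(all(colSums(M8 == 0) == 6))
  expect_false(any(duplicated(t(M8))))
  expect_error(build_ovo_coding(c(2, 2)), "at least 2")
})

test_that("hand-worked 3-class Hamming decoding picks the zero-loss class", {
  M <- build_ovo_coding(1:3)
  # votes: (1v2) -> 1, (1v3) -> 1, (2v3) -> 2
  d <- ecoc_decode(c(1, 1, -1), M, loss = "hamming")
  expect_equal(d$class, "1")
  # normalized by the 2 active columns per class: class 3 agrees on one
  expect_equal(unname(d$loss[1, ]), c(0, 1, 0.5))
  # all-zero scores tie every class; smallest label wins
  expect_equal(ecoc_decode(c(0, 0, 0), M, loss = "hamming")$class, "1")
  # losses are non-negative and the winner attains the row minimum
  set.seed(1)
  s <- matrix(rnorm(30), 10)
  d2 <- ecoc_decode(s, M, loss = "hinge")
  expect_true(all(d2$loss >= 0))
  expect_equal(d2$class,
               rownames(M)[apply(d2$loss, 1, which.min)])
})

test_that("Hamming decoding equals pairwise majority voting for K <= 4", {
  for (K in 2:4) {
    M <- build_ovo_coding(seq_len(K))
    B <- ncol(M)
    votes <- as.matrix(expand.grid(rep(list(c(-1, 1)), B)))
    dec <- ecoc_decode(votes, M, loss = "hamming")$class
    maj <- apply(votes, 1, oracle_pairwise_majority, coding = M)
    expect_equal(dec, maj)
  }
})

test_that("a 2-class ECOC model reduces to its single binary learner", {
  d <- two_clouds(5)
  m <- ecoc_fit(d$x, d$y, learner = "linear_svm")
  expect_length(m$learners, 1L)
  fit <- e1071::svm(d$x, factor(ifelse(d$y == 1, 1, -1),
                                levels = c(1, -1)),
                    kernel = "linear", cost = 1, scale = FALSE)
  expect_equal(predict(m, d$x),
               ifelse(predict(fit, d$x) == "1", "1", "3"))
})

test_that("knn1 memorizes training data and predicts by nearest neighbor", {
  d <- two_clouds(2)
  m <- ecoc_fit(d$x, d$y, learner = "knn1")
  expect_equal(predict(m, d$x), as.character(d$y))
  expect_equal(m$decoding_loss, "hamming")
  # dimension mismatch is caught
  expect_error(predict(m, d$x[, 1:3]), "features")
})

test_that("an 8-class fit holds 28 learners and decodes consistently", {
  set.seed(8)
  K <- 8
  n <- 6
  x <- do.call(rbind, lapply(1:K, function(k)
    matrix(rnorm(n * 4, mean = 6 * k), n)))
  y <- rep(c(0, 1, 2, 4, 5, 7, 8, 9), each = n)
  m <- ecoc_fit(x, y, learner = "knn1")
  expect_length(m$learners, 28L)
  expect_equal(predict(m, x), as.character(y))
})

test_that("leave-one-out is exact on separated clouds and order invariant", {
  d <- two_clouds(3)
  r <- loo_cross_validate(d$x, d$y, learner = "knn1", seed = 1)
  expect_equal(r$predicted, as.character(d$y))
  expect_length(r$predicted, nrow(d$x))
  # permuting sample order permutes predictions identically
  set.seed(11)
  ord <- sample(nrow(d$x))
  r2 <- loo_cross_validate(d$x[ord, ], d$y[ord], learner = "knn1",
                           seed = 1)
  expect_equal(r2$predicted, r$predicted[ord])
})

test_that("label permutation drives LOO accuracy to chance", {
  set.seed(21)
  K <- 4; n <- 15
  x <- do.call(rbind, lapply(1:K, function(k)
    matrix(rnorm(n * 3, mean = 10 * k), n)))
  y <- rep(1:K, each = n)
  accs <- vapply(1:3, function(rep) {
    yp <- sample(y)
    r <- loo_cross_validate(x, yp, learner = "knn1", seed = rep)
    mean(r$predicted == as.character(yp))
  }, numeric(1))
  expect_lte(mean(accs), 2 / K)
})

test_that("margin learners separate clouds through the hinge decoding", {
  d <- two_clouds(6)
  for (lrn in c("linear_svm", "lda")) {
    m <- ecoc_fit(d$x, d$y, learner = lrn)
    expect_equal(m$decoding_loss, "hinge")
    expect_equal(predict(m, d$x), as.character(d$y))
  }
  m <- ecoc_fit(d$x, d$y, learner = "gnb")
  expect_equal(predict(m, d$x), as.character(d$y))
})

test_that("grid-searched RBF SVM works and is seed-reproducible", {
  d <- two_clouds(7, n = 12, gap = 6, p = 3)
  m1 <- ecoc_fit(d$x, d$y, learner = "grid_svm", seed = 4)
  m2 <- ecoc_fit(d$x, d$y, learner = "grid_svm", seed = 4)
  expect_equal(predict(m1, d$x), as.character(d$y))
  expect_equal(m1$learners[[1]]$cost, m2$learners[[1]]$cost)
  expect_equal(m1$learners[[1]]$width, m2$learners[[1]]$width)
})

test_that("models fitted on standardized features accept raw new data", {
  imgs <- lapply(1:8, function(s) random_rgb(s, 35, 35))
  raw <- extract_features(imgs, "RGB", labels = rep(c(0, 7), 4))
  fm <- standardize(raw)
  m <- ecoc_fit(fm, learner = "knn1")
  expect_equal(predict(m, raw$values), predict(m, fm))
})

test_that("degenerate fits are rejected with clear errors", {
  expect_error(ecoc_fit(matrix(1:4, 2), c(1, 1), learner = "knn1"),
               "at least 2")
  d <- two_clouds(9, n = 3)
  expect_error(loo_cross_validate(d$x[c(1, 4), ], d$y[c(1, 4)],
                                  learner = "knn1"),
               "K \\+ 1")
})
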