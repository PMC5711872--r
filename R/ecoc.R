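#' One-vs-one ECOC coding matrix
#'
#' Builds the error-correcting output codes design with one binary
#' learner per unordered class pair: for `K` classes, `K (K - 1) / 2`
#' columns enumerating the pairs `(i < j)` in lexicographic order of the
#' sorted class labels, with class `i` coded `+1` and class `j` coded
#' `-1`; all other classes are `0` (excluded from that learner).
#'
#' @param labels Vector of class labels (at least 2 distinct values).
#' @return `K x B` integer matrix with values in `{-1, 0, +1}`, row names
#'   the sorted class labels and column names `"<i>_vs_<j>"`.
#' @export
build_ovo_coding <- function(labels) {
  cls <- sort(unique(labels))
  K <- length(cls)
  if (K < 2L) stop("need at least 2 distinct class labels")
  pairs <- utils::combn(K, 2L)
  M <- matrix(0L, K, ncol(pairs),
              dimnames = list(as.character(cls),
                              paste0(cls[pairs[1L, ]], "_vs_",
                                     cls[pairs[2L, ]])))
  for (b in seq_len(ncol(pairs))) {
    M[pairs[1L, b], b] <- 1L
    M[pairs[2L, b], b] <- -1L
  }
  M
}

# ---- binary learners -------------------------------------------------

# Margin learners emit a signed real score (positive <=> the +1 class of
# the column); vote learners emit a hard +/-1 vote.
.learner_specs <- c("knn1", "linear_svm", "grid_svm", "lda", "gnb")
.margin_learners <- c("linear_svm", "grid_svm", "lda")

.fit_binary <- function(x, y, spec, seed) {
  # x: matrix; y: +/-1 integer vector
  switch(spec,
    knn1 = list(spec = spec, x = x, y = y),
    linear_svm = list(spec = spec,
      fit = e1071::svm(x, factor(y, levels = c(1, -1)), kernel = "linear",
                       cost = 1, scale = FALSE)),
    grid_svm = .fit_grid_svm(x, y, seed),
    lda = {
      keep <- which(apply(x, 2L, function(v) stats::sd(v) > 0))
      if (!length(keep)) keep <- 1L
      list(spec = spec, keep = keep,
           fit = suppressWarnings(
             MASS::lda(x[, keep, drop = FALSE],
                       grouping = factor(y, levels = c(1, -1)))))
    },
    gnb = {
      keep <- which(apply(x, 2L, function(v) stats::sd(v) > 0))
      if (!length(keep)) keep <- 1L
      list(spec = spec, keep = keep,
           fit = e1071::naiveBayes(x[, keep, drop = FALSE],
                                   factor(y, levels = c(1, -1))))
    },
    stop("unknown learner spec: ", spec))
}

# Grid-searched RBF SVM: inner 5-fold cross-validated accuracy over
# cost {0.01, 0.1, 1, 10, 100} x kernel width sigma {0.1, 1, 10}
# (gamma = 1 / (2 sigma^2)); ties resolve to the first grid entry.
.fit_grid_svm <- function(x, y, seed,
                          costs = c(0.01, 0.1, 1, 10, 100),
                          widths = c(0.1, 1, 10)) {
  f <- factor(y, levels = c(1, -1))
  n <- nrow(x)
  nfold <- min(5L, n)
  folds <- .with_seed(seed, sample(rep_len(seq_len(nfold), n)))
  grid <- expand.grid(cost = costs, width = widths)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    gamma <- 1 / (2 * grid$width[g]^2)
    hits <- 0L
    for (k in seq_len(nfold)) {
      tr <- folds != k
      if (length(unique(f[tr])) < 2L) next
      fit <- e1071::svm(x[tr, , drop = FALSE], f[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = gamma, scale = FALSE)
      hits <- hits + sum(predict(fit, x[!tr, , drop = FALSE]) == f[!tr])
    }
    hits / n
  }, numeric(1))
  best <- which.max(acc)
  gamma <- 1 / (2 * grid$width[best]^2)
  list(spec = "grid_svm",
       cost = grid$cost[best], width = grid$width[best],
       fit = e1071::svm(x, f, kernel = "radial", cost = grid$cost[best],
                        gamma = gamma, scale = FALSE))
}

.score_binary <- function(learner, newx) {
  switch(learner$spec,
    knn1 = apply(newx, 1L, function(p) {
      d2 <- colSums((t(learner$x) - p)^2)
      learner$y[which.min(d2)]      # distance ties: earliest training row
    }),
    linear_svm = ,
    grid_svm = {
      dv <- attr(predict(learner$fit, newx, decision.values = TRUE),
                 "decision.values")
      as.numeric(dv[, 1L])          # positive <=> level "1"
    },
    lda = {
      post <- predict(learner$fit,
                      newx[, learner$keep, drop = FALSE])$posterior
      eps <- 1e-12
      log(post[, "1"] + eps) - log(post[, "-1"] + eps)
    },
    gnb = {
      post <- predict(learner$fit, newx[, learner$keep, drop = FALSE],
                      type = "raw")
      ifelse(post[, "1"] >= post[, "-1"], 1, -1)
    })
}

# ---- decoding --------------------------------------------------------

#' Loss-weighted ECOC decoding
#'
#' Aggregates per-learner scores into per-class losses: for class `k`,
#' `loss_k = sum_l |m_kl| g(m_kl s_l) / sum_l |m_kl|`, with `g` the hinge
#' loss `max(0, 1 - z) / 2` for margin scores or the Hamming loss
#' `(1 - sign(z)) / 2` for hard votes. The predicted class minimizes the
#' loss; ties resolve to the smallest class label.
#'
#' @param scores `n x B` matrix of learner scores (one column per coding
#'   column), or a length-`B` vector for a single observation.
#' @param coding `K x B` coding matrix (see [build_ovo_coding()]).
#' @param loss `"hinge"` or `"hamming"`.
#' @return List with `class` (length-`n` vector of predicted row names of
#'   `coding`) and `loss` (`n x K` matrix of per-class decoding losses).
#' @export
ecoc_decode <- function(scores, coding, loss = c("hinge", "hamming")) {
  loss <- match.arg(loss)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (ncol(scores) != ncol(coding))
    stop("scores have ", ncol(scores), " columns but the coding matrix has ",
         ncol(coding))
  g <- if (loss == "hinge") function(z) pmax(1 - z, 0) / 2
       else                 function(z) (1 - sign(z)) / 2
  K <- nrow(coding)
  L <- matrix(NA_real_, nrow(scores), K,
              dimnames = list(NULL, rownames(coding)))
  for (k in seq_len(K)) {
    m <- coding[k, ]
    w <- abs(m)
    Z <- sweep(scores, 2L, m, "*")
    L[, k] <- as.vector(g(Z) %*% w) / sum(w)
  }
  idx <- apply(L, 1L, which.min)    # first minimum = smallest class label
  list(class = rownames(coding)[idx], loss = L)
}

# ---- model fitting ---------------------------------------------------

#' Fit a one-vs-one error-correcting output codes classifier
#'
#' The modelling core of the package: trains one binary learner per
#' unordered class pair (the one-vs-one ECOC design) and classifies new
#' observations by loss-weighted decoding over all learners. Margin
#' learners (SVMs, LDA) are decoded with the hinge loss on their signed
#' scores; vote learners (1-nearest-neighbor, Gaussian naive Bayes) with
#' the Hamming loss on their hard votes.
#'
#' Available learners:
#' \describe{
#'   \item{`knn1`}{1-nearest-neighbor, Euclidean distance (native
#'     implementation; distance ties resolve to the earlier training
#'     sample).}
#'   \item{`linear_svm`}{soft-margin linear SVM, cost 1.}
#'   \item{`grid_svm`}{RBF SVM with cost and kernel width selected by an
#'     inner 5-fold cross-validated grid search (cost
#'     `{0.01, 0.1, 1, 10, 100}`, width `{0.1, 1, 10}`) — a grid-search
#'     stand-in for Bayesian hyperparameter optimization.}
#'   \item{`lda`, `gnb`}{linear discriminant analysis and Gaussian naive
#'     Bayes (columns constant within the two-class subset are dropped
#'     before fitting).}
#' }
#'
#' @param x Numeric feature matrix (samples x features) or a
#'   `"scar_features"` object (its stored standardization statistics are
#'   then carried into the model and applied to new data in `predict`).
#' @param y Class labels, one per row of `x`; ignored (taken from the
#'   object) when `x` is a `"scar_features"` carrying labels.
#' @param learner Learner specification, see above.
#' @param decoding `"hinge"`, `"hamming"`, or `NULL` (default) to choose
#'   by learner family.
#' @param seed Integer seed for stochastic learner internals (the inner
#'   cross-validation folds of `grid_svm`); deterministic learners ignore
#'   it.
#' @return Object of class `"ecoc"` with components `coding`,
#'   `class_order`, `learners`, `learner_spec`, `decoding_loss`,
#'   `n_features`, `levels_counts` and the standardization statistics, if
#'   any.
#' @seealso [predict.ecoc()], [loo_cross_validate()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c(0, 7), each = 20)
#' m <- ecoc_fit(x, y, learner = "knn1")
#' predict(m, x[c(1, 25), ])
#' @export
ecoc_fit <- function(x, y = NULL, learner = .learner_specs,
                     decoding = NULL, seed = 1L) {
  learner <- match.arg(learner)
  std <- NULL
  if (inherits(x, "scar_features")) {
    if (is.null(y)) y <- x$labels
    if (x$standardized)
      std <- list(center = x$center, scale = x$scale, frozen = x$frozen)
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("class labels y are required")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  coding <- build_ovo_coding(y)
  cls <- rownames(coding)
  tab <- table(factor(as.character(y), levels = cls))
  if (any(tab == 0L))
    stop("class(es) with zero training samples: ",
         paste(names(tab)[tab == 0L], collapse = ", "))
  ychar <- as.character(y)
  learners <- vector("list", ncol(coding))
  for (b in seq_len(ncol(coding))) {
    m <- coding[, b]
    pos <- cls[m == 1L]; neg <- cls[m == -1L]
    rows <- ychar %in% c(pos, neg)
    yb <- ifelse(ychar[rows] == pos, 1L, -1L)
    learners[[b]] <- .fit_binary(x[rows, , drop = FALSE], yb, learner,
                                 seed = seed + b)
  }
  if (is.null(decoding))
    decoding <- if (learner %in% .margin_learners) "hinge" else "hamming"
  structure(list(coding = coding, class_order = cls, learners = learners,
                 learner_spec = learner, decoding_loss = decoding,
                 n_features = ncol(x), class_counts = as.vector(tab),
                 standardization = std, call = match.call()),
            class = "ecoc")
}

#' Predict classes from a fitted ECOC model
#'
#' Scores every binary learner on the new observations and decodes with
#' [ecoc_decode()]. If the model was fitted on a standardized feature
#' matrix, the stored column means/standard deviations are applied to
#' `newdata` first (pass raw features on the original scale).
#'
#' @param object An `"ecoc"` model.
#' @param newdata Numeric matrix (observations x features), a single
#'   feature vector, or a `"scar_features"` object.
#' @param type `"class"` (default) for predicted labels, `"loss"` for the
#'   per-class decoding-loss matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels, or the loss
#'   matrix.
#' @export
predict.ecoc <- function(object, newdata, type = c("class", "loss"), ...) {
  type <- match.arg(type)
  raw_input <- !inherits(newdata, "scar_features") ||
    !isTRUE(newdata$standardized)
  if (inherits(newdata, "scar_features")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features but the model expects ",
         object$n_features)
  std <- object$standardization
  if (!is.null(std) && raw_input) {
    newdata <- sweep(sweep(newdata, 2L, std$center, "-"), 2L, std$scale,
                     "/")
    newdata[, std$frozen] <- 0
  }
  scores <- vapply(object$learners, .score_binary, newx = newdata,
                   FUN.VALUE = numeric(nrow(newdata)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  dec <- ecoc_decode(scores, object$coding, object$decoding_loss)
  if (type == "class") dec$class else dec$loss
}

#' @export
print.ecoc <- function(x, ...) {
  cat("One-vs-one ECOC classifier\n")
  cat("  learner:  ", x$learner_spec, " (", x$decoding_loss,
      " decoding)\n", sep = "")
  cat("  classes:  ", length(x$class_order), " (",
      paste(x$class_order, collapse = ", "), ")\n", sep = "")
  cat("  learners: ", length(x$learners), " pairwise binary fits on ",
      x$n_features, " features\n", sep = "")
  invisible(x)
}

#' @export
summary.ecoc <- function(object, ...) {
  structure(list(model = object,
                 counts = stats::setNames(object$class_counts,
                                          object$class_order)),
            class = "summary.ecoc")
}

#' @export
print.summary.ecoc <- function(x, ...) {
  print(x$model)
  cat("  training samples per class:\n")
  print(x$counts)
  invisible(x)
}

#' Display the one-vs-one coding matrix of a fitted model
#'
#' Draws the class-by-learner coding design (+1 white, 0 gray, -1 black).
#'
#' @param x An `"ecoc"` model.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ecoc <- function(x, ...) {
  M <- x$coding
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
                  col = grDevices::gray.colors(3, start = 0, end = 1),
                  xlab = "binary learner", ylab = "class", axes = FALSE,
                  main = "one-vs-one coding design", ...)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nrow(M)), labels = rev(rownames(M)),
                 las = 1)
  graphics::box()
  invisible(x)
}

# ---- leave-one-out harness ------------------------------------------

#' Leave-one-out cross-validation of an ECOC classifier
#'
#' For each of the `N` samples, fits the model on the remaining `N - 1`
#' and predicts the held-out one. Deterministic given `seed` (which only
#' feeds stochastic learner internals such as the `grid_svm` inner
#' folds); the result is invariant to sample order for deterministic
#' learners.
#'
#' @param fm A `"scar_features"` object carrying labels, or a numeric
#'   matrix (then `y` is required).
#' @param y Class labels when `fm` is a plain matrix.
#' @param learner,decoding As in [ecoc_fit()].
#' @param seed Integer seed.
#' @return Object of class `"loo_result"`: list with `truth` and
#'   `predicted` (character vectors in input order) and `sample_ids`.
#' @export
loo_cross_validate <- function(fm, y = NULL,
                               learner = .learner_specs,
                               decoding = NULL, seed = 1L) {
  learner <- match.arg(learner)
  if (inherits(fm, "scar_features")) {
    if (is.null(y)) y <- fm$labels
    ids <- fm$sample_ids
    x <- fm$values
  } else {
    x <- as.matrix(fm)
    ids <- rownames(x)
  }
  if (is.null(y)) stop("class labels are required")
  n <- nrow(x)
  if (n < length(unique(y)) + 1L)
    stop("leave-one-out needs at least K + 1 samples")
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- ecoc_fit(x[-i, , drop = FALSE], y[-i], learner = learner,
                  decoding = decoding, seed = seed)
    pred[i] <- predict(m, x[i, , drop = FALSE])
  }
  structure(list(truth = as.character(y), predicted = pred,
                 sample_ids = ids, learner = learner),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  acc <- mean(x$truth == x$predicted)
  cat("Leave-one-out cross-validation (", x$learner, "): ",
      length(x$truth), " folds, exact accuracy ",
      sprintf("%.2f%%", 100 * acc), "\n", sep = "")
  invisible(x)
}

# Evaluate expr under a temporary RNG state; the caller's state is
# restored afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
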