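#' Stratified fold assignment
#'
#' Partitions instance indices into `n_folds` folds preserving class
#' proportions: within each class the (seeded) shuffled indices are dealt
#' round-robin, starting from a rotating fold so overall fold sizes stay
#' balanced. Per-class fold counts differ by at most one.
#'
#' @param labels Class label per instance.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `n_folds` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1L) {
  y <- factor(labels)
  if (n_folds < 2) stop("'n_folds' must be >= 2")
  cls_n <- table(y)
  if (any(cls_n < n_folds))
    stop("class(es) smaller than n_folds: ",
         paste(names(cls_n)[cls_n < n_folds], collapse = ", "))
  folds <- vector("list", n_folds)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      for (j in seq_len(n_folds))
        folds[[j]] <- c(folds[[j]], idx[f == j])
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  lapply(folds, sort)
}

# --- learner wrappers ------------------------------------------------------
# The harness is the package's own; the learners are standard library
# implementations where one exists (random forest, SVM). The
# distance-weighted kNN and the multiclass AdaBoost (SAMME over
# depth-1 rpart stumps) are small in-package implementations.

train_learner <- function(algorithm, x, y, hyper = list(), seed = 1L) {
  switch(algorithm,
    random_forest = {
      ntree <- hyper$ntree %||% 500
      with_seed(seed, randomForest::randomForest(x, y, ntree = ntree))
    },
    svm = {
      cost <- hyper$cost %||% 1
      e1071::svm(x, y, kernel = "radial", cost = cost, scale = TRUE)
    },
    knn = {
      structure(list(x = x, y = y, k = hyper$k %||% 5L), class = "wknn")
    },
    adaboost = {
      with_seed(seed,
        fit_samme(x, y, n_rounds = hyper$n_rounds %||% 100L,
                  maxdepth = hyper$maxdepth %||% 1L))
    },
    stop("unknown algorithm '", algorithm, "'; supported: ",
         paste(SUPPORTED_ALGORITHMS, collapse = ", "))
  )
}

predict_learner <- function(model, newx) {
  if (inherits(model, "wknn")) return(predict_wknn(model, newx))
  if (inherits(model, "samme")) return(predict_samme(model, newx))
  stats::predict(model, newx)
}

#' Supported learner types
#' @export
SUPPORTED_ALGORITHMS <- c("random_forest", "svm", "knn", "adaboost")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Distance-weighted k-nearest-neighbour classifier: each of the k nearest
# training instances votes with weight 1/d (exact matches dominate).
predict_wknn <- function(model, newx) {
  newx <- as.matrix(newx)
  tr <- as.matrix(model$x)
  lev <- levels(model$y)
  out <- character(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    d <- sqrt(colSums((t(tr) - newx[i, ])^2))
    o <- order(d, seq_along(d))[seq_len(min(model$k, length(d)))]
    wts <- 1 / pmax(d[o], 1e-12)
    vote <- tapply(wts, factor(model$y[o], levels = lev), sum, default = 0)
    out[i] <- lev[which.max(vote)]
  }
  factor(out, levels = lev)
}

# Multiclass AdaBoost (SAMME) over rpart stumps.
fit_samme <- function(x, y, n_rounds = 100L, maxdepth = 1L) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  d <- data.frame(.y = y, as.data.frame(x))
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = -1,
                               minsplit = 2, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w * n,
                        method = "class", control = ctrl)
    pred <- stats::predict(fit, d, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err <= 0) {            # perfect stump: keep it, stop boosting
      stumps <- c(stumps, list(fit)); alphas <- c(alphas, log(K - 1) + 10)
      break
    }
    if (err >= 1 - 1 / K) break  # no better than chance: stop
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps <- c(stumps, list(fit)); alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "samme")
}

predict_samme <- function(model, newx) {
  nd <- as.data.frame(newx)
  score <- matrix(0, nrow(nd), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (t in seq_along(model$stumps)) {
    p <- stats::predict(model$stumps[[t]], nd, type = "class")
    score[cbind(seq_len(nrow(nd)), as.integer(p))] <-
      score[cbind(seq_len(nrow(nd)), as.integer(p))] + model$alphas[t]
  }
  factor(model$levels[max.col(score, ties.method = "first")],
         levels = model$levels)
}

# --- cross-validation ------------------------------------------------------

#' Stratified k-fold cross-validation of one learner
#'
#' Each fold serves once as the test set while the learner is trained on
#' the other folds only; every instance is predicted exactly once and the
#' predictions are accumulated into a pooled confusion matrix. The feature
#' ranking used for subsetting is supplied externally (computed once on the
#' full data set); pass `features = NULL` to use all columns.
#'
#' @param x Numeric feature matrix (or a `feature_matrix`; then `y` is
#'   taken from it).
#' @param y Class labels.
#' @param algorithm One of [SUPPORTED_ALGORITHMS].
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for fold assignment and any seeded learner.
#' @param features Optional character vector of feature columns to use.
#' @param hyper Named list of hyperparameters overriding the defaults
#'   (random forest: `ntree = 500`; SVM: radial kernel, `cost = 1`,
#'   standardised on the training folds; kNN: `k = 5`, distance-weighted;
#'   AdaBoost: `n_rounds = 100` depth-1 stumps).
#' @return Object of class `"cv_result"`: per-fold and pooled confusion
#'   matrices, per-fold accuracies, their mean, and the configuration.
#' @export
run_cv <- function(x, y = NULL, algorithm = "random_forest", n_folds = 10,
                   seed = 1L, features = NULL, hyper = list()) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$x
  }
  algorithm <- match.arg(algorithm, SUPPORTED_ALGORITHMS)
  x <- as.matrix(x)
  y <- factor(y)
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(x))
    if (length(missing_f))
      stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  folds <- stratified_folds(y, n_folds, seed)
  lev <- levels(y)
  pooled <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  fold_cms <- vector("list", n_folds)
  fold_acc <- numeric(n_folds)
  for (j in seq_len(n_folds)) {
    te <- folds[[j]]
    tr <- setdiff(seq_len(nrow(x)), te)
    model <- train_learner(algorithm, x[tr, , drop = FALSE],
                           droplevels(y[tr]), hyper, seed = seed + j)
    pred <- factor(as.character(predict_learner(model, x[te, , drop = FALSE])),
                   levels = lev)
    cm <- table(observed = y[te], predicted = pred)
    fold_cms[[j]] <- confusion_matrix(unclass(cm), unit = "count")
    fold_acc[j] <- sum(diag(cm)) / length(te)
    pooled <- pooled + cm
  }
  structure(list(fold_confusions = fold_cms,
                 pooled = confusion_matrix(pooled, unit = "count"),
                 fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 algorithm = algorithm, n_folds = n_folds, seed = seed,
                 features = colnames(x), hyper = hyper),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV, %s, %d features\n",
              x$n_folds, x$algorithm, length(x$features)))
  cat(sprintf("Mean accuracy: %.4f (folds %.4f-%.4f)\n",
              x$mean_accuracy, min(x$fold_accuracy), max(x$fold_accuracy)))
  invisible(x)
}

#' Accuracy across learners and feature counts
#'
#' For each algorithm and each feature count n, cross-validates the learner
#' on the n top-ranked features and records the mean accuracy; reports each
#' algorithm's maximum and the feature count attaining it (smallest n on
#' ties, favouring parsimony).
#'
#' @param x Numeric feature matrix or `feature_matrix`.
#' @param y Class labels (ignored when `x` is a `feature_matrix`).
#' @param ranking A `feature_ranking` covering the columns of `x`.
#' @param algorithms Character vector of learners to sweep.
#' @param n_features Integer vector of feature counts (default all of
#'   `1:ncol(x)`).
#' @param n_folds,seed,hyper Passed to [run_cv()].
#' @return Object of class `"sweep_result"`: `accuracy` (algorithms x
#'   counts matrix) and `best` (data frame algorithm / n_features /
#'   accuracy).
#' @export
sweep_feature_counts <- function(x, y = NULL, ranking,
                                 algorithms = SUPPORTED_ALGORITHMS,
                                 n_features = NULL, n_folds = 10, seed = 1L,
                                 hyper = list()) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$x
  }
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!all(colnames(x) %in% ranking$feature))
    stop("ranking does not cover all features of x")
  if (is.null(n_features)) n_features <- seq_len(ncol(x))
  acc <- matrix(NA_real_, length(algorithms), length(n_features),
                dimnames = list(algorithms, n_features))
  for (a in algorithms)
    for (j in seq_along(n_features)) {
      nf <- n_features[j]
      acc[a, j] <- run_cv(x, y, algorithm = a, n_folds = n_folds,
                          seed = seed, features = top_n(ranking, nf),
                          hyper = hyper)$mean_accuracy
    }
  best <- data.frame(
    algorithm = algorithms,
    n_features = n_features[apply(acc, 1, which.max)],  # first max: least n
    accuracy = apply(acc, 1, max),
    stringsAsFactors = FALSE)
  structure(list(accuracy = acc, n_features = n_features, best = best,
                 n_folds = n_folds, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Feature-count sweep (", x$n_folds, "-fold CV):\n", sep = "")
  b <- x$best
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-14s max accuracy %.4f at %d features\n",
                b$algorithm[i], b$accuracy[i], b$n_features[i]))
  invisible(x)
}
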