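#' Fit an eating-behaviour classifier
#'
#' The top-level modelling interface: ranks the features with multiclass
#' ReliefF, keeps the `n_features` top-ranked ones, estimates out-of-sample
#' performance by stratified k-fold cross-validation, and fits a final
#' learner of the chosen type on the full data set.
#'
#' @param x A `feature_matrix` (see [feature_matrix()]) or a numeric matrix
#'   with named feature columns.
#' @param y Class labels; ignored when `x` is a `feature_matrix`.
#' @param algorithm One of [SUPPORTED_ALGORITHMS] (default random forest,
#'   the strongest learner on this task).
#' @param n_features Number of top-ranked features to keep (default: all).
#' @param relieff_k ReliefF neighbour count k (default 100).
#' @param n_folds Cross-validation folds (default 10); `cv = FALSE` skips
#'   the estimate.
#' @param seed Integer seed driving folds and seeded learners.
#' @param hyper Learner hyperparameters, see [run_cv()].
#' @param cv Whether to cross-validate (default `TRUE`).
#' @return Object of class `"imubehave"` with components `ranking`,
#'   `features`, `cv` (a `cv_result` or `NULL`), `fit` (the final
#'   learner), `algorithm`, `levels`, `seed`.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_config(duration_s = 900, seed = 7))
#' ws <- discretise(build_channels(trial$stream), trial$track)
#' fm <- feature_matrix(ws)
#' fit <- imubehave(fm, n_features = 10, seed = 7)
#' print(fit)
#' summary(fit)
#' }
#' @export
imubehave <- function(x, y = NULL, algorithm = "random_forest",
                      n_features = NULL, relieff_k = 100, n_folds = 10,
                      seed = 1L, hyper = list(), cv = TRUE) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$x
  }
  algorithm <- match.arg(algorithm, SUPPORTED_ALGORITHMS)
  x <- as.matrix(x)
  y <- factor(y)
  w <- relieff_weights(x, y, n_neighbors = relieff_k)
  ranking <- rank_features(w)
  if (is.null(n_features)) n_features <- ncol(x)
  feats <- top_n(ranking, n_features)
  cv_res <- if (cv)
    run_cv(x, y, algorithm = algorithm, n_folds = n_folds, seed = seed,
           features = feats, hyper = hyper) else NULL
  fit <- train_learner(algorithm, x[, feats, drop = FALSE], y, hyper,
                       seed = seed)
  structure(list(ranking = ranking, features = feats, cv = cv_res,
                 fit = fit, algorithm = algorithm, levels = levels(y),
                 n_folds = n_folds, seed = seed),
            class = "imubehave")
}

#' @export
print.imubehave <- function(x, ...) {
  cat("Eating-behaviour classifier (", x$algorithm, ", ",
      length(x$features), " ReliefF-selected features)\n", sep = "")
  cat("Classes:", paste(x$levels, collapse = ", "), "\n")
  if (!is.null(x$cv))
    cat(sprintf("%d-fold CV mean accuracy: %.4f\n",
                x$n_folds, x$cv$mean_accuracy))
  cat("Top features:", paste(utils::head(x$features, 5), collapse = ", "),
      if (length(x$features) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
#' @rdname imubehave
#' @param object,... Method arguments.
summary.imubehave <- function(object, ...) {
  if (is.null(object$cv))
    stop("model was fitted with cv = FALSE; no held-out estimate to report")
  confusion_to_metrics(object$cv$pooled)
}

#' ReliefF feature weights of a fitted classifier
#' @param object An `imubehave` model.
#' @param ... Unused.
#' @return Named numeric vector of weights in ranking order.
#' @export
coef.imubehave <- function(object, ...) {
  stats::setNames(object$ranking$weight, object$ranking$feature)
}

#' @export
#' @rdname imubehave
#' @param newdata A `feature_matrix` or numeric matrix holding at least the
#'   model's selected feature columns.
predict.imubehave <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f))
    stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "))
  predict_learner(object$fit, newdata[, object$features, drop = FALSE])
}

#' @export
#' @rdname imubehave
#' @param n_top How many top-ranked features to display.
plot.imubehave <- function(x, n_top = 15, ...) {
  r <- utils::head(x$ranking, n_top)
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(r$weight), names.arg = rev(r$feature), horiz = TRUE,
                    las = 1, cex.names = 0.7, xlab = "ReliefF weight",
                    main = paste("Top", nrow(r), "features"), ...)
  invisible(x)
}
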