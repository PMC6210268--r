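#' Multiclass ReliefF feature weights
#'
#' Scores each feature by how well it separates close neighbours of
#' different classes. For each pivot instance R of class c, the weight of
#' feature f is decreased by the mean feature difference to R's k nearest
#' same-class neighbours (nearest hits) and increased by the prior-weighted
#' mean difference to its k nearest neighbours in each other class C
#' (nearest misses, weight `P(C) / (1 - P(c))`), everything divided by the
#' number of pivots. Feature differences are range-normalised to `[0, 1]`
#' with the global per-feature range, so weights lie in `[-1, 1]`.
#' Instance distance is the Manhattan distance on the range-normalised
#' features; neighbour-distance ties are broken by instance index, which
#' makes the exhaustive variant fully deterministic and order-independent.
#'
#' @param x Numeric matrix, instances in rows, named feature columns.
#' @param y Class labels (factor or character), at least 2 classes with at
#'   least 2 instances each.
#' @param n_neighbors Number of nearest hits and per-class misses, k
#'   (default 100). Clipped per class, with a warning, when a class is too
#'   small.
#' @param n_sampled Number of pivot instances m, or `NULL` (default) to use
#'   every instance exhaustively. Sampling uses `seed`.
#' @param seed Integer seed, only consulted when `n_sampled` is given.
#' @return Named numeric vector of feature weights.
#' @seealso [rank_features()], [top_n()]
#' @export
relieff_weights <- function(x, y, n_neighbors = 100, n_sampled = NULL,
                            seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  y <- droplevels(y)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (nlevels(y) < 2) stop("ReliefF needs at least 2 classes")
  cls_n <- table(y)
  if (any(cls_n < 2))
    stop("every class needs at least 2 instances; too small: ",
         paste(names(cls_n)[cls_n < 2], collapse = ", "))
  if (anyNA(x)) stop("missing feature values are not supported")
  k <- as.integer(n_neighbors)
  if (k < 1) stop("'n_neighbors' must be >= 1")
  if (any(cls_n - 1L < k))
    warning("n_neighbors clipped for class(es) smaller than k+1: ",
            paste(names(cls_n)[cls_n - 1L < k], collapse = ", "))

  # range normalisation; zero-range features contribute diff == 0
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (any(rng == 0))
    warning("zero-range feature(s) get weight 0: ",
            paste(colnames(x)[rng == 0], collapse = ", "))
  xn <- sweep(x, 2, apply(x, 2, min))
  xn <- sweep(xn, 2, ifelse(rng == 0, 1, rng), "/")
  xn[, rng == 0] <- 0

  pivots <- if (is.null(n_sampled)) seq_len(n) else {
    m <- as.integer(n_sampled)
    if (m < 1 || m > n) stop("'n_sampled' must lie in 1..nrow(x)")
    with_seed(seed, sample.int(n, m))
  }
  m <- length(pivots)
  prior <- as.numeric(cls_n) / n
  names(prior) <- names(cls_n)
  by_class <- split(seq_len(n), y)

  D <- as.matrix(stats::dist(xn, method = "manhattan"))
  w <- numeric(ncol(x))
  for (i in pivots) {
    ci <- as.character(y[i])
    upd <- numeric(ncol(x))
    for (cl in levels(y)) {
      cand <- by_class[[cl]]
      if (cl == ci) cand <- cand[cand != i]
      cand <- cand[order(D[i, cand], cand)]          # ties: index order
      nb <- cand[seq_len(min(k, length(cand)))]
      dmean <- colMeans(abs(xn[nb, , drop = FALSE] -
                              rep(xn[i, ], each = length(nb))))
      upd <- upd + if (cl == ci) -dmean else
        prior[cl] / (1 - prior[ci]) * dmean
    }
    w <- w + upd / m
  }
  stats::setNames(w, colnames(x))
}

#' Rank features by ReliefF weight
#'
#' Orders features by descending weight; ties are broken lexicographically
#' by feature name so the ranking is deterministic.
#'
#' @param weights Named numeric vector from [relieff_weights()].
#' @return Object of class `"feature_ranking"`: data frame with columns
#'   `rank`, `feature`, `weight`.
#' @export
rank_features <- function(weights) {
  if (!length(weights) || is.null(names(weights)))
    stop("'weights' must be a non-empty named vector")
  o <- order(-weights, names(weights))
  out <- data.frame(rank = seq_along(weights),
                    feature = names(weights)[o],
                    weight = unname(weights[o]),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("ReliefF feature ranking (", nrow(x), " features), top ",
      min(n, nrow(x)), ":\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Top-n features of a ranking
#'
#' @param ranking A `feature_ranking` from [rank_features()].
#' @param n How many top-ranked feature names to return.
#' @return Character vector of `n` feature names in rank order.
#' @export
top_n <- function(ranking, n) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (n < 1 || n > nrow(ranking))
    stop("'n' must lie in 1..", nrow(ranking))
  ranking$feature[seq_len(n)]
}

#' @rdname sensor_io
#' @param ranking A `feature_ranking` to write (`rank,feature,weight`).
#' @export
write_ranking <- function(ranking, file) {
  utils::write.csv(as.data.frame(ranking), file, row.names = FALSE)
  invisible(file)
}

#' @rdname sensor_io
#' @export
read_ranking <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(d) <- c("feature_ranking", "data.frame")
  d
}
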