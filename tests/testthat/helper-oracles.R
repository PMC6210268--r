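# Independent brute-force oracles, written as plain scalar loops so they
# share no code path with the package implementations they check.

# distributional statistics from the defining sums
oracle_stats <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  s2 <- s4 <- 0
  for (v in x) {
    s2 <- s2 + (v - m)^2
    s4 <- s4 + (v - m)^4
  }
  list(mean = m,
       std = sqrt(s2 / (n - 1)),
       kurtosis = if (s2 > 0) (s4 / n) / (s2 / n)^2 else 0,
       min = min(x), max = max(x))
}

# ReliefF recomputed naively: explicit pairwise distances, explicit
# neighbour search per class, scalar weight updates.
oracle_relieff <- function(x, y, k) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  p <- ncol(x)
  rng <- numeric(p)
  for (f in 1:p) rng[f] <- max(x[, f]) - min(x[, f])
  dff <- function(f, i, j) {
    if (rng[f] == 0) return(0)
    abs(x[i, f] - x[j, f]) / rng[f]
  }
  dist_ij <- function(i, j) {
    d <- 0
    for (f in 1:p) d <- d + dff(f, i, j)
    d
  }
  classes <- sort(unique(y))
  prior <- sapply(classes, function(cl) sum(y == cl) / n)
  names(prior) <- classes
  w <- numeric(p)
  for (i in 1:n) {
    for (cl in classes) {
      cand <- setdiff(which(y == cl), i)
      dd <- sapply(cand, function(j) dist_ij(i, j))
      nb <- cand[order(dd, cand)][seq_len(min(k, length(cand)))]
      for (f in 1:p) {
        dmean <- mean(sapply(nb, function(j) dff(f, i, j)))
        if (cl == y[i]) {
          w[f] <- w[f] - dmean / n
        } else {
          w[f] <- w[f] + prior[cl] / (1 - prior[y[i]]) * dmean / n
        }
      }
    }
  }
  names(w) <- colnames(x)
  w
}

# per-class metrics enumerated from an instance-level label/prediction list
oracle_metrics <- function(obs, pred, classes) {
  out <- list()
  for (cl in classes) {
    tp <- sum(obs == cl & pred == cl)
    fn <- sum(obs == cl & pred != cl)
    fp <- sum(obs != cl & pred == cl)
    tn <- sum(obs != cl & pred != cl)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    out[[cl]] <- c(precision = prec, recall = rec,
                   f_score = 2 * prec * rec / (prec + rec),
                   specificity = tn / (tn + fp))
  }
  out
}

# well-separated three-class Gaussian blobs for classifier sanity checks
make_blobs <- function(n_per_class = 30, p = 5, sep = 8, seed = 1) {
  set.seed(seed)
  classes <- c("grazing", "non_eating", "ruminating")
  x <- NULL
  y <- character(0)
  for (ci in seq_along(classes)) {
    centre <- rep(0, p)
    centre[ci] <- sep
    x <- rbind(x, sweep(matrix(rnorm(n_per_class * p), n_per_class, p),
                        2, centre, "+"))
    y <- c(y, rep(classes[ci], n_per_class))
  }
  colnames(x) <- paste0("f", 1:p)
  list(x = x, y = factor(y))
}

# small labelled synthetic trial shared by several tests
small_trial_features <- function(duration_s = 420, seed = 11) {
  trial <- generate_trial(trial_config(duration_s = duration_s, seed = seed))
  ws <- discretise(build_channels(trial$stream), trial$track)
  feature_matrix(ws)
}
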