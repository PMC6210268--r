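#' Feature characteristic sets
#'
#' Eleven characteristics are computed per channel. Two published lists of
#' the eleven exist and they differ in one member: the prose list includes
#' the absolute signal area, while the ranking table lists a spectral area
#' and no absolute area. Both sets are available; `"table3"` (with spectral
#' area) is the default because the feature-ranking analysis uses it.
#'
#' @param set `"table3"` or `"section25"`.
#' @return Character vector of 11 characteristic names.
#' @export
characteristic_set <- function(set = c("table3", "section25")) {
  set <- match.arg(set)
  base <- c("mean", "std", "kurtosis", "min", "max", "iqr",
            "signal_area", "zero_crossings", "dominant_frequency",
            "spectral_entropy")
  if (set == "table3") c(base, "spectral_area") else c(base, "abs_signal_area")
}

STREAM_NAMES <- c("A", "AD", "G", "GD")

#' Basic distributional statistics of a window
#'
#' Mean, sample standard deviation, kurtosis, minimum, maximum and
#' interquartile range. Kurtosis is the standardised fourth central moment
#' `m4 / m2^2` (population moments, no bias correction, no excess-3
#' subtraction); it is reported as 0 with a warning for a constant window,
#' where it is undefined.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector `mean, std, kurtosis, min, max, iqr`.
#' @export
basic_stats <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else {
    warning("constant input: kurtosis undefined, reported as 0")
    0
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  c(mean = m, std = stats::sd(x), kurtosis = kurt,
    min = min(x), max = max(x), iqr = q[2] - q[1])
}

#' Signal area and absolute signal area
#'
#' Riemann sums of the signal and of its absolute value over the window:
#' `sum(x) / fs` and `sum(abs(x)) / fs`.
#'
#' @param x Numeric vector.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Named numeric vector `signal_area, abs_signal_area`.
#' @export
signal_areas <- function(x, sampling_rate_hz) {
  c(signal_area = sum(x) / sampling_rate_hz,
    abs_signal_area = sum(abs(x)) / sampling_rate_hz)
}

#' Number of zero crossings of the mean-centred signal
#'
#' Counts strict sign changes of `x - mean(x)` between consecutive samples.
#' Centring matters: the magnitude channels are non-negative, so crossings
#' of raw zero would be degenerate. Samples exactly at the mean do not
#' break a sign run.
#'
#' @param x Numeric vector, length >= 2.
#' @return Non-negative integer count.
#' @export
zero_crossings <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  s <- sign(x - mean(x))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' One-sided periodogram of a window
#'
#' Plain (untapered) periodogram of the mean-removed signal: power
#' `|X_k|^2 / N` at frequencies `k * fs / N`, `k = 0 .. floor(N/2)`. The
#' DC bin is returned but excluded from every spectral feature.
#'
#' @param x Numeric vector, length >= 4.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return List with `frequency`, `power` and `amplitude`
#'   (`2 |X_k| / N`, the one-sided amplitude spectrum).
#' @export
spectrum_window <- function(x, sampling_rate_hz) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for a spectrum")
  X <- stats::fft(x - mean(x))
  k <- 0:(n %/% 2)
  list(frequency = k * sampling_rate_hz / n,
       power = Mod(X[k + 1])^2 / n,
       amplitude = 2 * Mod(X[k + 1]) / n)
}

# Shared tolerance below which a spectrum counts as empty (degenerate input).
SPECTRAL_TOL <- 1e-12

#' Dominant frequency of a window
#'
#' Frequency of the maximum-power non-DC periodogram bin; 0 by convention
#' when the total non-DC power is below tolerance (constant input).
#'
#' @inheritParams spectrum_window
#' @return Frequency in Hz, in `[0, fs/2]`.
#' @export
dominant_frequency <- function(x, sampling_rate_hz) {
  sp <- spectrum_window(x, sampling_rate_hz)
  p <- sp$power[-1]
  if (sum(p) <= SPECTRAL_TOL) return(0)
  sp$frequency[-1][which.max(p)]
}

#' Spectral entropy of a window
#'
#' Shannon entropy (natural log) of the non-DC periodogram normalised to
#' sum to one: near 0 for a tonal signal, up to `log(K)` (K non-DC bins)
#' for broadband noise. Defined as 0 for degenerate (zero-power) input.
#'
#' @inheritParams spectrum_window
#' @return Entropy in nats, in `[0, log(floor(N/2))]`.
#' @export
spectral_entropy <- function(x, sampling_rate_hz) {
  sp <- spectrum_window(x, sampling_rate_hz)
  p <- sp$power[-1]
  tot <- sum(p)
  if (tot <= SPECTRAL_TOL) return(0)
  p <- p[p > 0] / tot
  -sum(p * log(p))
}

#' Spectral area of a window
#'
#' Sum of the non-DC one-sided amplitude-spectrum bins times the bin width
#' `fs / N`; scales linearly with the signal.
#'
#' @inheritParams spectrum_window
#' @return Non-negative real.
#' @export
spectral_area <- function(x, sampling_rate_hz) {
  sp <- spectrum_window(x, sampling_rate_hz)
  sum(sp$amplitude[-1]) * sampling_rate_hz / length(x)
}

# All 11 characteristics of one channel slice.
channel_features <- function(x, fs, chars) {
  out <- c(basic_stats(x), signal_areas(x, fs),
           zero_crossings = as.numeric(zero_crossings(x)),
           dominant_frequency = dominant_frequency(x, fs),
           spectral_entropy = spectral_entropy(x, fs))
  if ("spectral_area" %in% chars)
    out <- c(out, spectral_area = spectral_area(x, fs))
  out[chars]
}

#' Extract the 44-feature vector of one window
#'
#' Computes the 11 characteristics of the active set on each of the four
#' channels `A`, `AD`, `G`, `GD`, yielding 44 named features
#' (`"<stream>.<characteristic>"`), in a fixed deterministic order.
#'
#' @param a,ad,g,gd Numeric vectors: the window's slice of each channel.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param set Characteristic set, see [characteristic_set()].
#' @return Named numeric vector of length 44.
#' @export
extract_features <- function(a, ad, g, gd, sampling_rate_hz,
                             set = c("table3", "section25")) {
  chars <- characteristic_set(match.arg(set))
  slices <- list(A = a, AD = ad, G = g, GD = gd)
  if (length(unique(lengths(slices))) != 1L)
    stop("the four channel slices must have equal length")
  if (length(a) < 4) stop("window must have at least 4 samples")
  out <- unlist(lapply(STREAM_NAMES, function(s)
    stats::setNames(channel_features(slices[[s]], sampling_rate_hz, chars),
                    paste(s, chars, sep = "."))))
  out
}

#' Feature matrix of a window set
#'
#' Applies [extract_features()] to every window, giving the
#' windows-by-44-features matrix used for ranking and classification.
#'
#' @param ws A `window_set` from [discretise()].
#' @param set Characteristic set, see [characteristic_set()].
#' @param drop_mixed Drop mixed windows instead of keeping them under their
#'   predominant label (default keeps them).
#' @return Object of class `"feature_matrix"`: list with `x` (numeric
#'   matrix, one row per window, 44 named columns), `labels` (behaviour
#'   factor), `is_mixed` (logical), `feature_names`.
#' @export
feature_matrix <- function(ws, set = c("table3", "section25"),
                           drop_mixed = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  set <- match.arg(set)
  keep <- if (drop_mixed) !ws$is_mixed else rep(TRUE, length(ws$starts))
  starts <- ws$starts[keep]
  if (!length(starts)) stop("no windows to extract features from")
  fs <- ws$sampling_rate_hz
  L <- ws$length
  rows <- lapply(starts, function(s) {
    i <- s:(s + L - 1L)
    extract_features(ws$channels$A[i], ws$channels$AD[i],
                     ws$channels$G[i], ws$channels$GD[i], fs, set)
  })
  x <- do.call(rbind, rows)
  structure(list(x = x,
                 labels = as_behaviour(ws$labels[keep]),
                 is_mixed = ws$is_mixed[keep],
                 feature_names = colnames(x)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "windows x", ncol(x$x), "features\n")
  cat("Labels:", paste(sprintf("%s=%d", levels(x$labels),
                               tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname sensor_io
#' @param fm A `feature_matrix` to write (feature columns + label + mixed).
#' @export
write_feature_matrix <- function(fm, file) {
  d <- data.frame(fm$x, label = fm$labels, is_mixed = fm$is_mixed,
                  check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' @rdname sensor_io
#' @export
read_feature_matrix <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE)
  fcols <- setdiff(names(d), c("label", "is_mixed"))
  structure(list(x = as.matrix(d[fcols]),
                 labels = as_behaviour(d$label),
                 is_mixed = as.logical(d$is_mixed),
                 feature_names = fcols),
            class = "feature_matrix")
}
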