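#' Euclidean magnitude of a tri-axial signal
#'
#' `sqrt(x^2 + y^2 + z^2)`, applied elementwise. The magnitude is
#' orientation-invariant, which is what makes features computed on it
#' comparable across sensor mountings.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @return Non-negative numeric vector.
#' @examples
#' magnitude(3, 4, 0)  # 5
#' @export
magnitude <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  sqrt(x^2 + y^2 + z^2)
}

#' Rate of change of a sampled signal
#'
#' Time derivative estimated by central differences on interior points and
#' one-sided differences at the two ends, so the output has the same length
#' as the input and stays index-aligned with it for windowing.
#'
#' @param series Numeric vector, length >= 2.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Numeric vector of the same length as `series` (units per second).
#' @export
rate_of_change <- function(series, sampling_rate_hz) {
  n <- length(series)
  if (n < 2) stop("'series' must have at least 2 samples")
  d <- numeric(n)
  d[1] <- (series[2] - series[1]) * sampling_rate_hz
  d[n] <- (series[n] - series[n - 1]) * sampling_rate_hz
  if (n > 2)
    d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * sampling_rate_hz / 2
  d
}

#' Build the four derived channels from a six-axis stream
#'
#' Computes the accelerometer magnitude `A` and gyroscope magnitude `G`
#' (Euclidean norms of the three axes at each sample) plus their rates of
#' change `AD` and `GD`. All features downstream are computed on these four
#' channels, never on raw axes.
#'
#' @param stream A `sensor_stream` data frame (see [generate_trial()],
#'   [read_sensor_stream()]).
#' @return An object of class `"channel_set"`: list of numeric vectors
#'   `A`, `AD`, `G`, `GD` plus the sampling rate.
#' @export
build_channels <- function(stream) {
  need <- c("ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(stream)))
    stop("stream must have columns ", paste(need, collapse = ", "))
  fs <- attr(stream, "sampling_rate_hz")
  if (is.null(fs)) stop("stream is missing its 'sampling_rate_hz' attribute")
  A <- magnitude(stream$ax, stream$ay, stream$az)
  G <- magnitude(stream$gx, stream$gy, stream$gz)
  structure(list(A = A, AD = rate_of_change(A, fs),
                 G = G, GD = rate_of_change(G, fs),
                 sampling_rate_hz = fs),
            class = "channel_set")
}

# Behaviour label of each sample under the half-open [start, end) convention.
sample_labels <- function(track, n, fs) {
  track <- validate_track(track)
  tt <- (seq_len(n) - 1L) / fs
  idx <- findInterval(tt, track$start_s)
  if (any(idx == 0) || any(tt >= track$end_s[nrow(track)]))
    stop("stream extends beyond the labelled interval track")
  track$behaviour[idx]
}

#' Discretise channels into labelled overlapping windows
#'
#' Cuts the four channels into windows of `window_s` seconds with the given
#' overlap (defaults: 7 s, 50\%, i.e. 112 samples with hop 56 at 16 Hz).
#' Trailing samples that do not fill a whole window are dropped. A window
#' whose samples all carry one behaviour label gets that label; otherwise
#' it is flagged mixed and assigned its predominant (most frequent) label,
#' ties broken by the label of the window's first sample.
#'
#' @param channels A `channel_set` from [build_channels()].
#' @param track A `label_track` covering the stream.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows, in [0, 1).
#' @return An object of class `"window_set"`: window start indices (1-based),
#'   per-window labels and mixed flags, the window length in samples, the
#'   hop, the channels, and `mixed_ratio`.
#' @export
discretise <- function(channels, track, window_s = 7, overlap = 0.5) {
  stopifnot(inherits(channels, "channel_set"))
  if (overlap < 0 || overlap >= 1) stop("'overlap' must lie in [0, 1)")
  fs <- channels$sampling_rate_hz
  L <- round(window_s * fs)
  if (L < 2) stop("window length must be at least 2 samples")
  hop <- round(L * (1 - overlap))
  if (hop < 1) stop("overlap leaves an empty hop; decrease it")
  n <- length(channels$A)
  n_win <- if (n >= L) (n - L) %/% hop + 1L else 0L
  labs <- sample_labels(track, n, fs)
  starts <- integer(n_win); lab <- character(n_win); mixed <- logical(n_win)
  for (i in seq_len(n_win)) {
    s <- (i - 1L) * hop + 1L
    starts[i] <- s
    wl <- labs[s:(s + L - 1L)]
    u <- unique(wl)
    if (length(u) == 1L) {
      lab[i] <- u
      mixed[i] <- FALSE
    } else {
      cnt <- table(wl)
      top <- names(cnt)[cnt == max(cnt)]
      lab[i] <- if (length(top) == 1L) top else wl[1L]  # tie: first sample
      mixed[i] <- TRUE
    }
  }
  structure(list(starts = starts, labels = lab, is_mixed = mixed,
                 length = L, hop = hop, channels = channels,
                 window_s = window_s, overlap = overlap,
                 sampling_rate_hz = fs,
                 mixed_ratio = if (n_win) mean(mixed) else NA_real_),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("Window set:", length(x$starts), "windows of", x$length,
      "samples (hop", x$hop, "samples,",
      sprintf("%.1f%%", 100 * x$overlap), "overlap)\n")
  cat("Labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                               table(x$labels)), collapse = ", "), "\n")
  cat(sprintf("Mixed windows: %.2f%%\n", 100 * x$mixed_ratio))
  invisible(x)
}

#' Percentage of mixed and non-mixed windows
#'
#' A mixed window spans a behaviour transition and carries more than one
#' sample label; the two percentages always sum to 100.
#'
#' @param ws A `window_set` from [discretise()].
#' @return Named numeric vector `c(non_mixed = , mixed = )`, in percent.
#' @export
mixed_ratio_report <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (!length(ws$starts)) stop("window set is empty")
  m <- 100 * mean(ws$is_mixed)
  c(non_mixed = 100 - m, mixed = m)
}

#' @rdname sensor_io
#' @param ws A `window_set` to write (index, start time, label, mixed flag).
#' @export
write_window_set <- function(ws, file) {
  d <- data.frame(window = seq_along(ws$starts),
                  start_s = (ws$starts - 1L) / ws$sampling_rate_hz,
                  label = ws$labels, is_mixed = ws$is_mixed)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
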