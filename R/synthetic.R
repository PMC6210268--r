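#' Behaviour signal regime for the synthetic trial generator
#'
#' A regime describes the qualitative signal structure of one behaviour as
#' seen by a head- or neck-mounted inertial sensor: a bout-constant
#' orientation offset of the accelerometer (its magnitude), a rhythmic
#' oscillation (the bite or chew rhythm), white measurement noise, and an
#' overall scale for the angular-rate channels. Units are arbitrary
#' (g-like for acceleration); the downstream pipeline is unit-agnostic.
#'
#' @param behaviour One of `"grazing"`, `"non_eating"`, `"ruminating"`.
#' @param base_magnitude Non-negative accelerometer magnitude offset.
#' @param oscillation_freq_hz Oscillation frequency in Hz, in (0, Nyquist).
#' @param oscillation_amp Non-negative oscillation amplitude.
#' @param noise_sd Non-negative standard deviation of the white noise.
#' @param gyro_scale Non-negative scale of the gyroscope channels.
#' @return An object of class `"behaviour_regime"` (a named list).
#' @seealso [default_regimes()], [trial_config()]
#' @export
behaviour_regime <- function(behaviour, base_magnitude, oscillation_freq_hz,
                             oscillation_amp, noise_sd, gyro_scale) {
  behaviour <- match.arg(behaviour, BEHAVIOURS)
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("regime field '", name, "' must be a single finite number")
    x
  }
  for (nm in c("base_magnitude", "oscillation_amp", "noise_sd", "gyro_scale")) {
    v <- num1(get(nm), nm)
    if (v < 0) stop("regime field '", nm, "' must be >= 0, got ", v)
  }
  f <- num1(oscillation_freq_hz, "oscillation_freq_hz")
  if (f <= 0 || f >= 8)
    stop("regime field 'oscillation_freq_hz' must lie in (0, 8) Hz ",
         "(below Nyquist at 16 Hz sampling), got ", f)
  structure(list(behaviour = behaviour,
                 base_magnitude = base_magnitude,
                 oscillation_freq_hz = oscillation_freq_hz,
                 oscillation_amp = oscillation_amp,
                 noise_sd = noise_sd,
                 gyro_scale = gyro_scale),
            class = "behaviour_regime")
}

#' Default behaviour regimes
#'
#' Shipped defaults encode the qualitative structure the classifier relies
#' on: ruminating has the lowest overall accelerometer magnitude, grazing
#' sits in between, and non-eating activity produces the highest
#' magnitudes; the chew rhythm of ruminating (~1 Hz) is slower than the
#' bite rhythm of grazing (~1.5 Hz), while non-eating movement is faster
#' and noisier (broadband). Ear mounting amplifies the rotational channels
#' relative to the collar; nothing else differs between placements.
#'
#' @param placement `"ear"` or `"collar"`.
#' @return Named list of three [behaviour_regime()] objects.
#' @export
default_regimes <- function(placement = c("collar", "ear")) {
  placement <- match.arg(placement)
  gmul <- if (placement == "ear") 1.5 else 1.0
  list(
    grazing = behaviour_regime("grazing",
      base_magnitude = 1.30, oscillation_freq_hz = 1.5,
      oscillation_amp = 0.30, noise_sd = 0.12, gyro_scale = 0.80 * gmul),
    non_eating = behaviour_regime("non_eating",
      base_magnitude = 1.80, oscillation_freq_hz = 3.2,
      oscillation_amp = 0.15, noise_sd = 0.35, gyro_scale = 0.50 * gmul),
    ruminating = behaviour_regime("ruminating",
      base_magnitude = 0.95, oscillation_freq_hz = 1.0,
      oscillation_amp = 0.12, noise_sd = 0.05, gyro_scale = 0.30 * gmul)
  )
}

#' Configuration of a synthetic sensor trial
#'
#' @param duration_s Trial length in seconds (> 0).
#' @param sampling_rate_hz Sampling rate in Hz (default 16).
#' @param bout_length_s Length-2 numeric range (min, max) of behaviour bout
#'   durations in seconds; the minimum must be at least one analysis window
#'   (7 s) so non-mixed windows dominate.
#' @param regimes Named list with one [behaviour_regime()] per behaviour;
#'   defaults to [default_regimes()] for `placement`.
#' @param placement Sensor placement, `"collar"` or `"ear"`.
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate identical trials.
#' @return An object of class `"trial_config"`.
#' @export
trial_config <- function(duration_s = 600, sampling_rate_hz = 16,
                         bout_length_s = c(30, 90),
                         regimes = default_regimes(placement),
                         placement = c("collar", "ear"), seed = 1L) {
  placement <- match.arg(placement)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("'duration_s' must be a positive number")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be a positive number")
  if (length(bout_length_s) != 2L || bout_length_s[1] > bout_length_s[2])
    stop("'bout_length_s' must be a (min, max) range")
  if (bout_length_s[1] < 7)
    stop("'bout_length_s' minimum must be >= 7 s (one analysis window)")
  if (!setequal(names(regimes), BEHAVIOURS))
    stop("'regimes' must contain exactly one regime per behaviour: ",
         paste(BEHAVIOURS, collapse = ", "))
  for (nm in BEHAVIOURS) {
    r <- regimes[[nm]]
    if (!inherits(r, "behaviour_regime"))
      stop("regimes[['", nm, "']] is not a behaviour_regime")
    if (r$behaviour != nm)
      stop("regime stored under '", nm, "' is tagged '", r$behaviour, "'")
    if (r$oscillation_freq_hz >= sampling_rate_hz / 2)
      stop("regime '", nm, "': field 'oscillation_freq_hz' (",
           r$oscillation_freq_hz, " Hz) must be below Nyquist (",
           sampling_rate_hz / 2, " Hz)")
  }
  structure(list(duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 bout_length_s = as.numeric(bout_length_s),
                 regimes = regimes[BEHAVIOURS],
                 placement = placement,
                 seed = as.integer(seed)),
            class = "trial_config")
}

# Run code under a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a labelled synthetic sensor trial
#'
#' Draws a schedule of behaviour bouts (uniform lengths within
#' `bout_length_s`, no behaviour immediately repeated) that tiles the trial
#' duration, then synthesises the six sensor axes bout by bout. Per axis,
#' acceleration = bout-constant orientation offset + sinusoid at the
#' regime's oscillation frequency + white noise; the gyroscope axes carry
#' the same rhythmic structure scaled by `gyro_scale` and without the
#' gravity offset. The accelerometer magnitude therefore inherits the
#' regime ordering ruminating < grazing < non-eating under the defaults.
#'
#' @param config A [trial_config()].
#' @return List with components `stream` (a `sensor_stream` data frame:
#'   `timestamp, ax, ay, az, gx, gy, gz`, with the sampling rate and
#'   placement as attributes) and `track` (a `label_track` data frame:
#'   `start_s, end_s, behaviour`, tiling `[0, duration_s]`).
#' @examples
#' trial <- generate_trial(trial_config(duration_s = 120, seed = 42))
#' nrow(trial$stream)   # 120 s x 16 Hz = 1920 samples
#' label_coverage(trial$track, 120)
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  with_seed(config$seed, {
    # bout schedule tiling [0, duration]
    starts <- ends <- numeric(0)
    labs <- character(0)
    t0 <- 0
    prev <- NA_character_
    while (t0 < config$duration_s - 1e-9) {
      pool <- setdiff(BEHAVIOURS, prev)
      b <- sample(pool, 1L)
      len <- stats::runif(1, config$bout_length_s[1], config$bout_length_s[2])
      t1 <- min(t0 + len, config$duration_s)
      starts <- c(starts, t0); ends <- c(ends, t1); labs <- c(labs, b)
      prev <- b
      t0 <- t1
    }
    track <- data.frame(start_s = starts, end_s = ends,
                        behaviour = labs, stringsAsFactors = FALSE)
    class(track) <- c("label_track", "data.frame")

    tt <- (seq_len(n) - 1L) / fs
    acc <- matrix(0, n, 3L, dimnames = list(NULL, c("ax", "ay", "az")))
    gyr <- matrix(0, n, 3L, dimnames = list(NULL, c("gx", "gy", "gz")))
    for (i in seq_len(nrow(track))) {
      reg <- config$regimes[[track$behaviour[i]]]
      idx <- which(tt >= track$start_s[i] - 1e-12 & tt < track$end_s[i] - 1e-12)
      if (!length(idx)) next
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))          # bout-constant orientation
      ph_a <- stats::runif(3, 0, 2 * pi)
      ph_g <- stats::runif(3, 0, 2 * pi)
      w <- 2 * pi * reg$oscillation_freq_hz
      for (ax in 1:3) {
        acc[idx, ax] <- reg$base_magnitude * u[ax] +
          reg$oscillation_amp * sin(w * tt[idx] + ph_a[ax]) +
          stats::rnorm(length(idx), sd = reg$noise_sd)
        gyr[idx, ax] <- reg$gyro_scale *
          (sin(w * tt[idx] + ph_g[ax]) +
             stats::rnorm(length(idx), sd = reg$noise_sd))
      }
    }
    stream <- data.frame(timestamp = tt, acc, gyr)
    attr(stream, "sampling_rate_hz") <- fs
    attr(stream, "placement") <- config$placement
    class(stream) <- c("sensor_stream", "data.frame")
    list(stream = stream, track = track)
  })
}

#' Fraction of trial time covered by each behaviour
#'
#' Validates that the label intervals tile `[0, duration_s]` without gaps
#' or overlaps, then returns the fraction of total time each behaviour
#' occupies (fractions sum to 1).
#'
#' @param track A `label_track` data frame (`start_s, end_s, behaviour`).
#' @param duration_s Total trial duration in seconds.
#' @return Named numeric vector, one entry per behaviour present.
#' @export
label_coverage <- function(track, duration_s) {
  validate_track(track, duration_s)
  len <- track$end_s - track$start_s
  out <- tapply(len, track$behaviour, sum) / duration_s
  c(out)[order(names(c(out)))]
}

validate_track <- function(track, duration_s = NULL) {
  need <- c("start_s", "end_s", "behaviour")
  if (!all(need %in% names(track)))
    stop("label track must have columns ", paste(need, collapse = ", "))
  if (any(track$end_s <= track$start_s))
    stop("label track has empty or negative-length intervals")
  o <- order(track$start_s)
  track <- track[o, , drop = FALSE]
  if (nrow(track) > 1) {
    gaps <- track$start_s[-1] - track$end_s[-nrow(track)]
    if (any(gaps > 1e-9)) stop("label track has gaps between intervals")
    if (any(gaps < -1e-9)) stop("label track has overlapping intervals")
  }
  if (!is.null(duration_s)) {
    if (abs(track$start_s[1]) > 1e-9 ||
        abs(track$end_s[nrow(track)] - duration_s) > 1e-9)
      stop("label track does not tile [0, ", duration_s, "]")
  }
  invisible(track)
}

#' @rdname sensor_io
#' @export
write_sensor_stream <- function(stream, file) {
  utils::write.csv(as.data.frame(stream), file, row.names = FALSE)
  invisible(file)
}

#' Read and write sensor streams and label tracks as CSV
#'
#' Streams use the header `timestamp,ax,ay,az,gx,gy,gz`; label tracks use
#' `start_s,end_s,behaviour`. The sampling rate of a read stream is
#' recovered from the median timestamp spacing.
#'
#' @param stream,track Objects to write.
#' @param file Path to a CSV file.
#' @param placement Placement tag to attach on read.
#' @return The read object, or (invisibly) the file path on write.
#' @name sensor_io
#' @export
read_sensor_stream <- function(file, placement = c("collar", "ear")) {
  placement <- match.arg(placement)
  d <- utils::read.csv(file)
  need <- c("timestamp", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(d)))
    stop("stream CSV must have columns ", paste(need, collapse = ","))
  dt <- stats::median(diff(d$timestamp))
  attr(d, "sampling_rate_hz") <- 1 / dt
  attr(d, "placement") <- placement
  class(d) <- c("sensor_stream", "data.frame")
  d
}

#' @rdname sensor_io
#' @export
write_label_track <- function(track, file) {
  utils::write.csv(as.data.frame(track), file, row.names = FALSE)
  invisible(file)
}

#' @rdname sensor_io
#' @export
read_label_track <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_track(d)
  class(d) <- c("label_track", "data.frame")
  d
}
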