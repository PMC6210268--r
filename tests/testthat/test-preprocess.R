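make_stream <- function(ax, ay, az, gx = 0 * ax, gy = 0 * ax, gz = 0 * ax,
                        fs = 16) {
  n <- length(ax)
  d <- data.frame(timestamp = (seq_len(n) - 1) / fs,
                  ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  attr(d, "sampling_rate_hz") <- fs
  class(d) <- c("sensor_stream", "data.frame")
  d
}

test_that("magnitude is the Euclidean norm", {
  expect_equal(magnitude(3, 4, 0), 5)
  expect_equal(magnitude(0, 0, 0), 0)
  expect_equal(magnitude(1, 2, 2), 3)
  expect_equal(magnitude(c(3, 1), c(4, 2), c(0, 2)), c(5, 3))
})

test_that("rate of change matches hand-computed finite differences", {
  expect_equal(rate_of_change(c(5, 5, 5, 5), 16), rep(0, 4))
  expect_equal(rate_of_change(c(0, 1, 2, 3), 16), rep(16, 4))

  # ramp up then down: derivative changes sign at the kink
  x <- c(0, 1, 2, 3, 2, 1, 0)
  d <- rate_of_change(x, 1)
  expect_equal(d, c(1, 1, 1, 0, -1, -1, -1))

  expect_error(rate_of_change(5, 16), "at least 2")
})

test_that("build_channels produces aligned magnitude and derivative channels", {
  n <- 64
  s <- make_stream(rnorm(n), rnorm(n), rnorm(n))
  ch <- build_channels(s)
  expect_s3_class(ch, "channel_set")
  expect_true(all(lengths(ch[c("A", "AD", "G", "GD")]) == n))
  expect_true(all(ch$A >= 0))
  expect_equal(ch$G, rep(0, n))   # all-zero gyro axes
  expect_equal(ch$GD, rep(0, n))

  # stationary unit gravity on one axis
  g <- make_stream(rep(0, n), rep(0, n), rep(1, n))
  chg <- build_channels(g)
  expect_equal(chg$A, rep(1, n))
  expect_equal(chg$AD, rep(0, n))
})

test_that("channel magnitudes are invariant under axis permutation", {
  n <- 128
  set.seed(2)
  ax <- rnorm(n); ay <- rnorm(n); az <- rnorm(n)
  gx <- rnorm(n); gy <- rnorm(n); gz <- rnorm(n)
  c1 <- build_channels(make_stream(ax, ay, az, gx, gy, gz))
  c2 <- build_channels(make_stream(az, ax, ay, gy, gz, gx))
  expect_equal(c1$A, c2$A)
  expect_equal(c1$G, c2$G)
})

test_that("discretisation yields 112-sample windows with hop 56 at defaults", {
  n <- 224
  trackc <- data.frame(start_s = 0, end_s = n / 16, behaviour = "grazing")
  ch <- build_channels(make_stream(rnorm(n), rnorm(n), rnorm(n)))
  ws <- discretise(ch, trackc)
  expect_equal(ws$length, 112)
  expect_equal(ws$hop, 56)
  expect_equal(ws$starts, c(1, 57, 113))  # floor((224-112)/56)+1 = 3 windows
  expect_true(all(!ws$is_mixed))
  expect_equal(mixed_ratio_report(ws), c(non_mixed = 100, mixed = 0))
})

test_that("window count matches exhaustive enumeration for lengths 0..300", {
  L <- 112; hop <- 56
  for (n in 0:300) {
    # oracle: enumerate start positions directly
    expected <- if (n < L) 0L else length(seq(1, n - L + 1, by = hop))
    got <- if (n >= 2) {
      trackc <- data.frame(start_s = 0, end_s = n / 16 + 1,
                           behaviour = "grazing")
      ch <- build_channels(make_stream(seq_len(n) * 0, seq_len(n) * 0,
                                       seq_len(n) * 0 + 1))
      length(discretise(ch, trackc)$starts)
    } else expected
    expect_identical(got, as.integer(expected))
  }
})

test_that("consecutive windows share exactly L - hop samples and stay in range", {
  trial <- generate_trial(trial_config(duration_s = 240, seed = 5))
  ws <- discretise(build_channels(trial$stream), trial$track)
  expect_true(all(diff(ws$starts) == ws$hop))
  expect_true(all(ws$starts + ws$length - 1 <= nrow(trial$stream)))
  expect_equal(ws$length - ws$hop, 56)
})

test_that("mixed windows take the predominant label, ties to the first sample", {
  fs <- 16
  n <- 112
  ch <- build_channels(make_stream(rep(1, n), rep(0, n), rep(0, n), fs = fs))
  # 60 grazing samples then 52 ruminating samples in a single window
  trackm <- data.frame(start_s = c(0, 60 / fs), end_s = c(60 / fs, n / fs),
                       behaviour = c("grazing", "ruminating"))
  ws <- discretise(ch, trackm)
  expect_true(ws$is_mixed[1])
  expect_equal(ws$labels[1], "grazing")

  # exact 56/56 tie: label of the window's first sample wins
  trackt <- data.frame(start_s = c(0, 56 / fs), end_s = c(56 / fs, n / fs),
                       behaviour = c("ruminating", "grazing"))
  wst <- discretise(ch, trackt)
  expect_true(wst$is_mixed[1])
  expect_equal(wst$labels[1], "ruminating")
})

test_that("mixed and non-mixed percentages always sum to 100", {
  for (seed in 1:5) {
    trial <- generate_trial(trial_config(duration_s = 300, seed = seed,
                                         bout_length_s = c(10, 40)))
    ws <- discretise(build_channels(trial$stream), trial$track)
    rep <- mixed_ratio_report(ws)
    expect_equal(sum(rep), 100)
  }
})

test_that("long bouts keep the mixed percentage low", {
  trial <- generate_trial(trial_config(duration_s = 1200, seed = 9,
                                       bout_length_s = c(30, 60)))
  ws <- discretise(build_channels(trial$stream), trial$track)
  expect_lt(mixed_ratio_report(ws)[["mixed"]], 25)
})

test_that("degenerate discretisation settings are rejected", {
  n <- 224
  trackc <- data.frame(start_s = 0, end_s = n / 16, behaviour = "grazing")
  ch <- build_channels(make_stream(rnorm(n), rnorm(n), rnorm(n)))
  expect_error(discretise(ch, trackc, overlap = 1), "overlap")
  expect_error(discretise(ch, trackc, window_s = 1 / 32), "at least 2")
})
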