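fs <- 16
tgrid <- (0:111) / fs

test_that("every window yields exactly 44 named features in both sets", {
  set.seed(1)
  a <- abs(rnorm(112)); g <- abs(rnorm(112))
  for (set in c("table3", "section25")) {
    fv <- extract_features(a, rate_of_change(a, fs), g,
                           rate_of_change(g, fs), fs, set = set)
    expect_length(fv, 44)
    expected_names <- as.vector(t(outer(c("A", "AD", "G", "GD"),
                                        characteristic_set(set),
                                        paste, sep = ".")))
    expect_identical(names(fv), expected_names)
  }
  # the two sets differ in exactly one characteristic
  expect_identical(setdiff(characteristic_set("table3"),
                           characteristic_set("section25")), "spectral_area")
  expect_identical(setdiff(characteristic_set("section25"),
                           characteristic_set("table3")), "abs_signal_area")
})

test_that("identical channels give identical per-stream features; zeros degenerate to zero", {
  set.seed(2)
  a <- abs(rnorm(112))
  suppressWarnings({
    fv <- extract_features(a, a, a, a, fs)
    z <- extract_features(rep(0, 112), rep(0, 112), rep(0, 112), rep(0, 112), fs)
  })
  expect_equal(unname(fv[grep("^A\\.", names(fv))]),
               unname(fv[grep("^G\\.", names(fv))]))
  expect_equal(unname(z[c("A.mean", "A.signal_area", "A.zero_crossings",
                          "A.dominant_frequency", "A.spectral_area")]),
               rep(0, 5))
})

test_that("basic statistics match a direct-sum oracle on random windows", {
  expect_equal(unname(basic_stats(1:5)[c("mean", "min", "max")]), c(3, 1, 5))
  suppressWarnings(
    expect_equal(unname(basic_stats(rep(2.5, 10))[c("std", "iqr")]), c(0, 0),
                 tolerance = 1e-15))
  expect_warning(basic_stats(rep(1, 5)), "kurtosis")

  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(112)
    got <- basic_stats(x)
    want <- oracle_stats(x)
    for (nm in names(want))
      expect_equal(unname(got[[nm]]), want[[nm]], tolerance = 1e-12)
    expect_equal(unname(got[["iqr"]]),
                 unname(diff(quantile(x, c(.25, .75)))), tolerance = 1e-12)
  }
})

test_that("signal areas are Riemann sums and obey the triangle inequality", {
  expect_equal(signal_areas(rep(1, 112), fs)[["signal_area"]], 7.0)
  alt <- rep(c(1, -1), 56)
  sa <- signal_areas(alt, fs)
  expect_equal(sa[["signal_area"]], 0)
  expect_equal(sa[["abs_signal_area"]], 7.0)
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(50)
    sa <- signal_areas(x, fs)
    expect_gte(sa[["abs_signal_area"]], abs(sa[["signal_area"]]))
  }
})

test_that("zero crossings count sign changes of the centred signal", {
  expect_equal(zero_crossings(rep(3, 10)), 0L)
  # exactly 4 periods in the window: 2 crossings per period
  x <- sin(2 * pi * 4 * (0:111) / 112)
  expect_equal(zero_crossings(x), 8)
  n <- 31
  expect_equal(zero_crossings(rep(c(1, -1), length.out = n)), n - 1)
  # non-negative magnitude-like signal still gets a meaningful count
  expect_gt(zero_crossings(1.5 + sin(2 * pi * 2 * tgrid)), 0)
})

test_that("the periodogram concentrates power where it should", {
  x <- sin(2 * pi * 2 * tgrid)
  sp <- spectrum_window(x, fs)
  expect_equal(sp$frequency[which.max(sp$power[-1]) + 1], 2.0)
  expect_equal(diff(sp$frequency)[1], fs / 112)

  # white noise: no single bin dominates
  set.seed(5)
  for (i in 1:20) {
    sp <- spectrum_window(rnorm(112), fs)
    p <- sp$power[-1]
    expect_lt(max(p) / sum(p), 0.5)
  }

  sp0 <- spectrum_window(rep(4, 112), fs)
  expect_lt(sum(sp0$power), 1e-20)
})

test_that("dominant frequency lands on exact bins and prefers larger amplitude", {
  expect_equal(dominant_frequency(sin(2 * pi * 2 * tgrid), fs), 2.0)
  expect_equal(dominant_frequency(rep(1, 112), fs), 0)
  two <- sin(2 * pi * 1 * tgrid) + 2 * sin(2 * pi * 3 * tgrid)
  expect_equal(dominant_frequency(two, fs), 3.0)
})

test_that("spectral entropy is 0 for a tone, ln K for a flat spectrum, bounded otherwise", {
  expect_lt(spectral_entropy(sin(2 * pi * 2 * tgrid), fs), 1e-12)
  # a unit impulse has an exactly flat magnitude spectrum: entropy ln(56)
  impulse <- c(1, rep(0, 111))
  expect_equal(spectral_entropy(impulse, fs), log(56), tolerance = 1e-12)
  expect_equal(spectral_entropy(rep(7, 112), fs), 0)
  set.seed(6)
  for (i in 1:10) {
    h <- spectral_entropy(rnorm(112), fs)
    expect_gte(h, 0)
    expect_lte(h, log(56))
  }
})

test_that("spectral area is linear in the signal and grows with added noise", {
  x <- sin(2 * pi * 2 * tgrid)
  expect_equal(spectral_area(2 * x, fs), 2 * spectral_area(x, fs))
  expect_equal(spectral_area(rep(1, 112), fs), 0)
  set.seed(7)
  for (i in 1:20) {
    noisy <- x + rnorm(112, sd = 0.5)
    expect_gt(spectral_area(noisy, fs), spectral_area(x, fs))
  }
})

test_that("features shift and scale the way their definitions demand", {
  set.seed(8)
  a <- abs(rnorm(112)) + 1
  base <- extract_features(a, a, a, a, fs)
  shift <- extract_features(a + 5, a + 5, a + 5, a + 5, fs)
  unchanged <- c("std", "kurtosis", "iqr", "zero_crossings",
                 "dominant_frequency", "spectral_entropy", "spectral_area")
  for (ch in unchanged)
    expect_equal(shift[[paste0("A.", ch)]], base[[paste0("A.", ch)]],
                 tolerance = 1e-9)
  expect_equal(shift[["A.mean"]], base[["A.mean"]] + 5)
  expect_equal(shift[["A.signal_area"]], base[["A.signal_area"]] + 5 * 7)

  scaled <- extract_features(3 * a, 3 * a, 3 * a, 3 * a, fs)
  for (ch in c("mean", "std", "min", "max", "iqr", "signal_area"))
    expect_equal(scaled[[paste0("A.", ch)]], 3 * base[[paste0("A.", ch)]],
                 tolerance = 1e-9)
  for (ch in c("zero_crossings", "dominant_frequency", "spectral_entropy"))
    expect_equal(scaled[[paste0("A.", ch)]], base[[paste0("A.", ch)]],
                 tolerance = 1e-9)
})

test_that("feature_matrix has one row per window and a CSV round-trip survives", {
  fm <- small_trial_features(duration_s = 120, seed = 10)
  expect_equal(ncol(fm$x), 44)
  expect_equal(nrow(fm$x), length(fm$labels))
  f <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  fm2 <- read_feature_matrix(f)
  expect_equal(fm2$x, fm$x, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.character(fm2$labels), as.character(fm$labels))
  unlink(f)
})

test_that("too-short windows are rejected", {
  expect_error(extract_features(1:3, 1:3, 1:3, 1:3, fs), "at least 4")
  expect_error(extract_features(1:5, 1:5, 1:5, 1:4, fs), "equal length")
})
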