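# Signal curation chain: resampling, band-pass filter, magnitude,
# epoch sums, thresholding.

test_that("resampling identical-grid inputs is the identity", {
  sch <- session_schedule(window_duration = 120, session_starts = 0,
                          session_duration = 60)
  t <- (0:(120 * 12.5 - 1)) / 12.5
  x <- sin(t)
  mi <- accel_stream(t, x, 0 * t, 1 + 0 * t, "MI")
  li <- accel_stream(t, 2 * x, 0 * t, 1 + 0 * t, "LI")
  g <- synchronize_resample(mi, li, schedule = sch)
  expect_equal(g$MI$x, x, tolerance = 1e-12)
  expect_equal(g$LI$x, 2 * x, tolerance = 1e-12)
  expect_false(any(g$MI$missing))
  expect_false(any(g$LI$missing))
})

test_that("half-interval offset ramp interpolates to the analytic ramp", {
  sch <- session_schedule(window_duration = 60, session_starts = 0,
                          session_duration = 30)
  t_grid <- (0:(60 * 12.5 - 1)) / 12.5
  off <- 0.04  # half a nominal interval
  t_off <- t_grid + off
  ramp <- function(t) 0.3 * t  # linear, so linear interpolation is exact
  mi <- accel_stream(t_off, ramp(t_off), 0 * t_off, 1 + 0 * t_off, "MI")
  li <- accel_stream(t_grid, ramp(t_grid), 0 * t_grid, 1 + 0 * t_grid, "LI")
  g <- synchronize_resample(mi, li, schedule = sch)
  interior <- !g$MI$missing
  expect_gt(sum(interior), 700)
  expect_equal(g$MI$x[interior], ramp(t_grid[interior]), tolerance = 1e-10)
})

test_that("holes are preserved on the affected side only and never interpolated across", {
  sch <- session_schedule(window_duration = 600, session_starts = 0,
                          session_duration = 60)
  t <- (0:(600 * 12.5 - 1)) / 12.5
  keep <- !(t >= 100 & t < 165)  # 65-s hole
  mk <- function(tt, side) accel_stream(tt, 0.5 * tt, 0 * tt, 1 + 0 * tt, side)
  g <- synchronize_resample(mk(t[keep], "MI"), mk(t, "LI"), schedule = sch)
  hole <- t > 100 & t < 164.95
  expect_true(all(g$MI$missing[hole]))
  expect_false(any(g$LI$missing))
  expect_false(any(g$MI$missing[!(t >= 100 & t <= 165.05)]))
})

test_that("band-pass removes DC and has the designed frequency response", {
  t <- (0:(600 * 12.5 - 1)) / 12.5
  mid <- 2000:5000  # away from edges
  # constant 1 g: DC lies outside the pass band
  yc <- bandpass_filter(rep(1, length(t)))
  expect_lt(max(abs(yc[mid])), 1e-3)
  # 1 Hz, 0.1 g: inside the band, amplitude preserved within 5%
  y1 <- bandpass_filter(0.1 * sin(2 * pi * 1 * t))
  expect_gt(max(abs(y1[mid])), 0.095)
  expect_lt(max(abs(y1[mid])), 0.105)
  # 5 Hz, 0.1 g: in the stop band, attenuated below 10%
  y5 <- bandpass_filter(0.1 * sin(2 * pi * 5 * t))
  expect_lt(max(abs(y5[mid])), 0.01)
})

test_that("filtering respects gaps: segments are independent and short fragments drop", {
  t <- (0:(600 * 12.5 - 1)) / 12.5
  x <- 0.1 * sin(2 * pi * t)
  x[t >= 200 & t < 300] <- NA
  y <- bandpass_filter(x)
  expect_true(all(is.na(y[t >= 200 & t < 300])))
  expect_false(anyNA(y[t < 200]))
  # a 5-s fragment is shorter than the filter warm-up: marked missing
  x2 <- rep(NA_real_, length(t))
  x2[t < 5] <- 0.1 * sin(2 * pi * t[t < 5])
  expect_true(all(is.na(bandpass_filter(x2))))
})

test_that("magnitude is the Euclidean norm, missing in -> missing out", {
  expect_equal(accel_magnitude(0, 0, 0), 0)
  expect_equal(accel_magnitude(0.3, 0.4, 0), 0.5)
  set.seed(31)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  # brute-force per-element recomputation
  expect_equal(accel_magnitude(x, y, z),
               vapply(1:50, function(i) sqrt(sum(c(x[i], y[i], z[i])^2)),
                      numeric(1)))
  expect_true(is.na(accel_magnitude(NA, 1, 1)))
})

test_that("epoch sums follow the half-open [k, k+1) convention", {
  sch <- session_schedule(window_duration = 20, session_starts = 0,
                          session_duration = 10)
  t <- (0:(20 * 12.5 - 1)) / 12.5
  z <- rep(0, length(t))
  expect_equal(epoch_sum(z, t, sch)$magnitude_sum, rep(0, 20))
  # single sample of 2.0 in epoch 7
  one <- z; one[t >= 7 & t < 8][3] <- 2
  es <- epoch_sum(one, t, sch)
  expect_equal(es$magnitude_sum[8], 2)
  expect_equal(sum(es$magnitude_sum), 2)
  # constant magnitude: sums equal the per-epoch sample count (12 or 13)
  counts <- as.integer(table(floor(t)))
  es1 <- epoch_sum(rep(1, length(t)), t, sch)
  expect_equal(es1$magnitude_sum, as.numeric(counts))
  expect_true(all(counts %in% c(12L, 13L)))
  # epochs with >= 50% missing samples are flagged missing
  miss <- rep(1, length(t)); miss[t >= 3 & t < 3.56] <- NA  # 7 of 13
  expect_true(epoch_sum(miss, t, sch)$missing[4])
  miss2 <- rep(1, length(t)); miss2[t >= 3 & t < 3.2] <- NA  # 3 of 13
  expect_false(epoch_sum(miss2, t, sch)$missing[4])
})

test_that("thresholding is boundary-inclusive and rejects non-positive thresholds", {
  sums <- c(0, 0.1, 0.2, 0.3)
  expect_equal(threshold_counts(sums, 0.2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(threshold_counts(rep(0.1, 5), 0.2), rep(FALSE, 5))
  expect_error(threshold_counts(sums, 0), "positive")
  expect_error(threshold_counts(sums, -1), "positive")
  # vectorized comparison agrees with an element-wise loop
  set.seed(12)
  s <- runif(200)
  expect_equal(threshold_counts(s, 0.5),
               vapply(s, function(v) v >= 0.5, logical(1)))
  # missing epochs are inactive regardless of their sum
  expect_equal(threshold_counts(c(1, 1), 0.5, missing = c(TRUE, FALSE)),
               c(FALSE, TRUE))
})

test_that("pipeline output is invariant to constant axis offsets (DC rejection)", {
  sch <- hour_schedule()
  day <- generate_day(generator_params(seed = 77, p_post = 0.7), sch)
  cfg <- load_config()
  base <- process_day(day, cfg, sides = "MI")$MI
  shifted <- day
  shifted$mi_stream$x <- shifted$mi_stream$x + 0.37
  shifted$mi_stream$z <- shifted$mi_stream$z - 1.0
  out <- process_day(shifted, cfg, sides = "MI")$MI
  expect_equal(out$active, base$active)
  expect_equal(out$magnitude_sum, base$magnitude_sum, tolerance = 1e-6)
})

test_that("a day of pure gravity and noise yields zero active epochs", {
  day <- generate_day(generator_params(seed = 3, p_post = 0, p_pre = 0),
                      hour_schedule())
  ep <- process_day(day, load_config(), sides = "MI")$MI
  expect_equal(sum(ep$active), 0L)
  expect_equal(nrow(ep), 3600L)  # one epoch per second of the window
})
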