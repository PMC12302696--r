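# Signal curation: raw dual-wrist streams -> per-second activity counts.
#
# Chain: common 12.5 Hz grid (linear interpolation, never across gaps) ->
# zero-phase Butterworth band-pass per axis (removes the static gravity
# component) -> Euclidean norm -> 1-s epoch sums -> threshold into binary
# activity counts.

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * ri)
  p
}

# Butterworth band-pass design via analog prototype + bilinear transform.
# `order` is the low-pass prototype order; the band-pass filter has twice
# that order (order = 2 -> the 4th-order filter used by default).
butter_bandpass <- function(band, fs, order = 2L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            band[2] < fs / 2)
  # pre-warped analog edge frequencies
  w1 <- 2 * fs * tan(pi * band[1] / fs)
  w2 <- 2 * fs * tan(pi * band[2] / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each prototype pole splits in two
  pb <- bw / 2 * p_lp
  disc <- sqrt(pb^2 - w0^2)
  poles <- c(pb + disc, pb - disc)
  zeros <- rep(0 + 0i, order)
  gain <- bw^order
  # bilinear transform with gain match at the band centre
  fs2 <- 2 * fs
  pd <- (fs2 + poles) / (fs2 - poles)
  zd <- (fs2 + zeros) / (fs2 - zeros)
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  list(b = Re(gd * poly_from_roots(zd)), a = Re(poly_from_roots(pd)))
}

# single-pass IIR filter, zero initial state; C-speed via stats::filter
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                     sides = 1L)
  v <- as.numeric(v)[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

# forward-backward filtering with odd-reflection padding at both ends
filtfilt_zero_phase <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1L] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase band-pass filter for accelerometer axis series
#'
#' Applies a 4th-order Butterworth band-pass (default 0.25-2.5 Hz at
#' 12.5 Hz) forward and backward, giving zero phase shift so cue-response
#' latencies are preserved. The pass band excludes DC, removing the
#' static gravity component. `NA` samples mark data gaps: the filter is
#' applied independently to each contiguous run of observed samples and
#' never across a gap. Runs shorter than three settling lengths of the
#' low band edge (`3 * ceiling(fs / band[1])` samples, 12 s at the
#' defaults) are dominated by edge transients and are marked missing.
#'
#' @param x Numeric series on a uniform grid; `NA` = missing.
#' @param band Pass band `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param fs Sampling rate (Hz).
#' @return Filtered series, same length; `NA` where input was missing or
#'   the segment was too short to filter.
#' @examples
#' t <- seq(0, 60, by = 1/12.5)
#' y <- bandpass_filter(1 + 0.1 * sin(2 * pi * t), band = c(0.25, 2.5))
#' @export
bandpass_filter <- function(x, band = c(0.25, 2.5), fs = 12.5) {
  co <- butter_bandpass(band, fs)
  settle <- ceiling(fs / band[1])
  min_len <- 3L * settle
  out <- rep(NA_real_, length(x))
  miss <- is.na(x)
  if (all(miss)) return(out)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) next
    if (r$lengths[i] < min_len) next  # too short to filter; stays missing
    idx <- starts[i]:ends[i]
    out[idx] <- filtfilt_zero_phase(co$b, co$a, x[idx], padlen = min_len)
  }
  out
}

#' Synchronize and resample both wrists onto a common grid
#'
#' Builds the uniform nominal-rate grid spanning the monitoring window
#' and maps each wrist's samples onto it by linear interpolation between
#' neighbouring samples. Interpolation is only trusted between samples at
#' most `max_interp_gap` nominal intervals apart; grid points inside
#' larger holes (and outside the recorded span) are marked missing, so
#' wear gaps are preserved rather than painted over.
#'
#' @param mi_stream,li_stream [accel_stream()] objects.
#' @param cue_log Optional [cue_event_log()]; carried through unchanged
#'   (cue timestamps already live on the day's time axis).
#' @param schedule A [session_schedule()].
#' @param fs Grid rate (Hz). Default 12.5.
#' @param max_interp_gap Maximum bracketing-sample spacing for
#'   interpolation, in nominal intervals. Default 2.
#' @param sides Which wrists to resample (default both); restricting to
#'   one wrist halves the cost when only that side is analysed.
#' @return An object of class `aligned_grid`: list with `time` (grid,
#'   s), per-side `x`, `y`, `z` and logical `missing`, plus `cue_times`,
#'   `schedule`, `fs`.
#' @export
synchronize_resample <- function(mi_stream, li_stream, cue_log = NULL,
                                 schedule = session_schedule(), fs = 12.5,
                                 max_interp_gap = 2, sides = c("MI", "LI")) {
  stopifnot(inherits(mi_stream, "accel_stream"),
            inherits(li_stream, "accel_stream"))
  w0 <- schedule$window_start
  n <- round(schedule$window_duration * fs)
  grid <- w0 + (seq_len(n) - 1L) / fs
  w1 <- w0 + schedule$window_duration
  overlap <- function(s) length(s$time) >= 2L &&
    s$time[1L] < w1 && s$time[length(s$time)] > w0
  if (!overlap(mi_stream) && !overlap(li_stream))
    stop("neither stream overlaps the monitoring window")
  streams <- list(MI = mi_stream, LI = li_stream)[sides]
  res <- lapply(streams, resample_one, grid = grid, fs = fs,
                max_interp_gap = max_interp_gap)
  structure(c(list(time = grid, fs = fs, schedule = schedule), res,
              list(cue_times = if (!is.null(cue_log)) cue_log$time)),
            class = "aligned_grid")
}

resample_one <- function(stream, grid, fs, max_interp_gap) {
  nt <- length(stream$time)
  if (nt < 2L)
    return(list(x = rep(NA_real_, length(grid)),
                y = rep(NA_real_, length(grid)),
                z = rep(NA_real_, length(grid)),
                missing = rep(TRUE, length(grid))))
  tol <- 1e-9
  idx <- findInterval(grid, stream$time)
  # grid point usable if it coincides with a sample, or its bracketing
  # samples are close enough to interpolate between
  ok_interior <- idx >= 1L & idx < nt
  gap_ok <- rep(FALSE, length(grid))
  ii <- which(ok_interior)
  gap_ok[ii] <- (stream$time[idx[ii] + 1L] - stream$time[idx[ii]]) <=
    max_interp_gap / fs + tol
  coincide <- idx >= 1L & idx <= nt & abs(grid - stream$time[pmax(idx, 1L)]) < tol
  valid <- gap_ok | coincide
  out <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    v <- rep(NA_real_, length(grid))
    if (any(valid))
      v[valid] <- stats::approx(stream$time, stream[[ax]], xout = grid[valid],
                                method = "linear", rule = 1)$y
    v
  })
  c(out, list(missing = !valid))
}

#' Euclidean acceleration magnitude
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three
#' (filtered) axis series; missing in, missing out.
#'
#' @param x,y,z Axis series of equal length (`NA` = missing).
#' @return Numeric magnitude series.
#' @export
accel_magnitude <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  sqrt(x^2 + y^2 + z^2)
}

#' Sum acceleration magnitude within 1-s epochs
#'
#' Epoch `k` covers `[k, k+1)` seconds (half-open, 0-based within the
#' monitoring window) and sums all samples whose timestamp falls inside
#' it — 12 or 13 samples at 12.5 Hz depending on grid phase. Epochs with
#' at least 50% missing samples are marked missing; available samples in
#' a partially missing epoch are still summed.
#'
#' @param magnitude Magnitude series on the uniform grid (`NA` missing).
#' @param time Grid timestamps (s), same length.
#' @param schedule A [session_schedule()] giving the epoch range.
#' @return Data frame with `epoch_start`, `magnitude_sum`, `missing`,
#'   one row per second of the monitoring window.
#' @export
epoch_sum <- function(magnitude, time, schedule = session_schedule()) {
  stopifnot(length(magnitude) == length(time))
  n_ep <- as.integer(ceiling(schedule$window_duration))
  # epoch ids; small eps guards against float jitter at epoch boundaries
  ep <- floor(time - schedule$window_start + 1e-9)
  keep <- ep >= 0 & ep < n_ep
  ep <- as.integer(ep[keep])
  m <- magnitude[keep]
  if (is.unsorted(ep)) {
    o <- order(ep); ep <- ep[o]; m <- m[o]
  }
  # segment sums via one cumsum pass (time is epoch-sorted)
  na <- is.na(m)
  v <- m; v[na] <- 0
  last <- c(which(diff(ep) > 0L), length(ep))
  ids <- ep[last] + 1L
  seg <- function(cum) { s <- cum[last]; s - c(0, s[-length(s)]) }
  sums <- numeric(n_ep); n_all <- integer(n_ep); n_miss <- integer(n_ep)
  if (length(last)) {
    sums[ids] <- seg(cumsum(v))
    n_all[ids] <- as.integer(seg(cumsum(rep(1L, length(ep)))))
    n_miss[ids] <- as.integer(seg(cumsum(as.integer(na))))
  }
  miss <- n_all == 0L | n_miss >= 0.5 * n_all
  data.frame(epoch_start = schedule$window_start + 0:(n_ep - 1L),
             magnitude_sum = sums, missing = miss)
}

#' Threshold epoch sums into binary activity counts
#'
#' `active(k) = magnitude_sum(k) >= threshold` (boundary inclusive).
#' Missing epochs are counted as inactive but remain flagged missing, so
#' true zeros and absent data stay distinguishable downstream.
#'
#' @param sums Numeric epoch sums.
#' @param threshold Positive activity threshold (g-s per epoch).
#' @param missing Logical missingness flags (default none missing).
#' @return Logical activity vector.
#' @export
threshold_counts <- function(sums, threshold, missing = rep(FALSE, length(sums))) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive scalar")
  !missing & !is.na(sums) & sums >= threshold
}

#' Run the full signal chain on a monitoring day
#'
#' Convenience wrapper: synchronize/resample, band-pass filter each axis
#' per contiguous segment, Euclidean magnitude, 1-s epoch sums, threshold
#' into activity counts — for each requested wrist.
#'
#' @param day A [monitoring_day()].
#' @param config A `wristcue_config` from [load_config()].
#' @param sides Wrists to process (default both). Processing only the
#'   wrist you need halves the cost in large simulations.
#' @return Named list of [epoch_activity()] series (one per side), with
#'   the aligned grid attached as attribute `grid`.
#' @export
process_day <- function(day, config = load_config(), sides = c("MI", "LI")) {
  stopifnot(inherits(day, "monitoring_day"))
  pl <- config$pipeline
  grid <- synchronize_resample(day$mi_stream, day$li_stream, day$cue_log,
                               schedule = day$schedule, fs = pl$fs,
                               max_interp_gap = pl$max_interp_gap,
                               sides = sides)
  out <- lapply(stats::setNames(sides, sides), function(sd) {
    g <- grid[[sd]]
    fx <- bandpass_filter(g$x, pl$band, pl$fs)
    fy <- bandpass_filter(g$y, pl$band, pl$fs)
    fz <- bandpass_filter(g$z, pl$band, pl$fs)
    mag <- accel_magnitude(fx, fy, fz)
    es <- epoch_sum(mag, grid$time, day$schedule)
    act <- threshold_counts(es$magnitude_sum, pl$threshold, es$missing)
    epoch_activity(sd, es$epoch_start, es$magnitude_sum, act, es$missing,
                   threshold = pl$threshold)
  })
  attr(out, "grid") <- grid
  out
}
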