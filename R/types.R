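#' Tri-axial accelerometer stream for one wrist
#'
#' A time-stamped tri-axial accelerometer record in gravitational units.
#' Timestamps are seconds since the start of the monitoring day and must be
#' strictly increasing; the nominal sampling interval is 1/12.5 s but gaps
#' (non-wear, Bluetooth dropouts) may be present.
#'
#' @param time Numeric vector of timestamps (s), strictly increasing.
#' @param x,y,z Acceleration along each axis (g); finite.
#' @param side `"MI"` (more-involved) or `"LI"` (less-involved) wrist.
#' @param fs Nominal sampling rate (Hz). Default 12.5.
#' @return An object of class `accel_stream`.
#' @export
accel_stream <- function(time, x, y, z, side = c("MI", "LI"), fs = 12.5) {
  side <- match.arg(side)
  time <- as.numeric(time)
  n <- length(time)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("time, x, y, z must have equal length")
  if (n > 0) {
    if (anyNA(time) || any(!is.finite(time)))
      stop("timestamps must be finite")
    d <- diff(time)
    if (any(d <= 0)) {
      bad <- which(d <= 0)[1L] + 1L
      stop(sprintf("timestamps must be strictly increasing (violated at sample %d, t = %g)",
                   bad, time[bad]))
    }
    if (any(!is.finite(c(x, y, z))))
      stop("acceleration values must be finite")
  }
  structure(list(side = side, fs = fs, time = time,
                 x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "accel_stream")
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> side %s, %d samples, fs %g Hz", x$side,
              length(x$time), x$fs))
  if (length(x$time))
    cat(sprintf(", t in [%.3f, %.3f] s", x$time[1L], x$time[length(x$time)]))
  cat("\n")
  invisible(x)
}

#' Cue-event log
#'
#' Ordered vibrotactile cue timestamps with session membership and the
#' within-day cue index (1..180 under the default schedule).
#'
#' @param time Numeric vector of cue timestamps (s), strictly increasing.
#' @param schedule [session_schedule()] used to assign session indices and
#'   to validate spacing.
#' @param on_outside How to treat cues outside every scheduled session:
#'   `"flag"` (default; kept, marked `in_session = FALSE`) or `"error"`.
#' @return An object of class `cue_event_log`: a data frame with columns
#'   `time`, `session_index`, `cue_index_in_day`, `in_session`.
#' @export
cue_event_log <- function(time, schedule = session_schedule(),
                          on_outside = c("flag", "error")) {
  on_outside <- match.arg(on_outside)
  time <- as.numeric(time)
  if (length(time) && any(diff(time) <= 0))
    stop("cue timestamps must be strictly increasing")
  max_cues <- schedule_cue_count(schedule)
  if (length(time) > max_cues)
    stop(sprintf("%d cues exceed the schedule's maximum of %d",
                 length(time), max_cues))
  sess <- session_index_of(time, schedule)
  if (anyNA(sess)) {
    if (on_outside == "error")
      stop(sprintf("%d cue(s) fall outside every scheduled session",
                   sum(is.na(sess))))
    if (length(time))
      warning(sprintf("%d cue(s) outside scheduled sessions flagged",
                      sum(is.na(sess))))
  }
  per_session <- floor(schedule$session_duration / schedule$inter_cue_interval)
  if (any(!is.na(sess)) &&
      any(tabulate(sess, length(schedule$session_starts)) > per_session))
    stop(sprintf("more than %d cues in one session", per_session))
  out <- data.frame(time = time,
                    session_index = sess,
                    cue_index_in_day = seq_along(time),
                    in_session = !is.na(sess))
  class(out) <- c("cue_event_log", "data.frame")
  attr(out, "schedule") <- schedule
  out
}

#' One participant-day of monitoring
#'
#' Bundles the two wrist streams, the (optional) cue log, the schedule and
#' metadata. A missing cue log marks a silent-monitoring day (home phase).
#'
#' @param participant_id Character scalar.
#' @param day_index Integer day number within the study.
#' @param schedule [session_schedule()].
#' @param mi_stream,li_stream [accel_stream()] objects for the
#'   more-involved and less-involved wrists.
#' @param cue_log [cue_event_log()] or `NULL` for silent monitoring.
#' @param activity_stage Program stage metadata: `"tap"`, `"assist"`,
#'   `"independent"`, or `NA`.
#' @return An object of class `monitoring_day`.
#' @export
monitoring_day <- function(participant_id, day_index, schedule,
                           mi_stream, li_stream, cue_log = NULL,
                           activity_stage = NA_character_) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(mi_stream, "accel_stream"),
            inherits(li_stream, "accel_stream"))
  if (mi_stream$side != "MI" || li_stream$side != "LI")
    stop("mi_stream must have side 'MI' and li_stream side 'LI'")
  if (!is.na(activity_stage) &&
      !activity_stage %in% c("tap", "assist", "independent"))
    stop("activity_stage must be tap, assist or independent")
  if (!is.null(cue_log)) {
    stopifnot(inherits(cue_log, "cue_event_log"))
    if (any(!cue_log$in_session))
      stop("all cue timestamps must lie inside scheduled sessions")
  }
  structure(list(participant_id = as.character(participant_id),
                 day_index = as.integer(day_index),
                 schedule = schedule,
                 mi_stream = mi_stream, li_stream = li_stream,
                 cue_log = cue_log, activity_stage = activity_stage),
            class = "monitoring_day")
}

#' @export
print.monitoring_day <- function(x, ...) {
  cat(sprintf("<monitoring_day> %s day %d (%s)\n", x$participant_id,
              x$day_index,
              if (is.null(x$cue_log)) "silent monitoring"
              else sprintf("%d cues", nrow(x$cue_log))))
  print(x$schedule)
  cat(sprintf("  MI: %d samples; LI: %d samples\n",
              length(x$mi_stream$time), length(x$li_stream$time)))
  invisible(x)
}

#' Per-second epoch activity series for one wrist
#'
#' One row per second of the monitoring window: the summed band-pass
#' filtered acceleration magnitude within each 1-s epoch, the binary
#' activity count, and a missingness flag (epochs with >= 50% missing
#' samples). Epoch `k` covers `[k, k+1)` seconds (half-open, 0-based).
#'
#' @param side `"MI"` or `"LI"`.
#' @param epoch_start Integer-valued epoch start times (s).
#' @param magnitude_sum Per-epoch summed magnitude (g), `>= 0`.
#' @param active Logical activity counts.
#' @param missing Logical missingness flags.
#' @param threshold The activity-count threshold used (g per epoch).
#' @return An object of class `epoch_activity`: a data frame.
#' @export
epoch_activity <- function(side, epoch_start, magnitude_sum, active, missing,
                           threshold = NA_real_) {
  n <- length(epoch_start)
  stopifnot(length(magnitude_sum) == n, length(active) == n,
            length(missing) == n)
  if (any(magnitude_sum[!missing] < 0)) stop("magnitude_sum must be >= 0")
  out <- data.frame(epoch_start = as.numeric(epoch_start),
                    magnitude_sum = as.numeric(magnitude_sum),
                    active = as.logical(active),
                    missing = as.logical(missing))
  class(out) <- c("epoch_activity", "data.frame")
  attr(out, "side") <- side
  attr(out, "threshold") <- threshold
  out
}

#' Cohort-level t-test result
#'
#' Container for the one-sample threshold tests and the paired pre/post
#' test. `ci` is a two-sided confidence interval on the estimate at
#' `conf_level` (90% for the one-sided threshold tests, 95% for the
#' paired test, matching the study's reporting conventions).
#'
#' @keywords internal
cohort_test_result <- function(estimate, t_statistic, df, p_value, ci,
                               conf_level, threshold, direction,
                               test = "one_sample_t") {
  stopifnot(df >= 1, ci[1] <= ci[2])
  structure(list(test = test, estimate = estimate,
                 t_statistic = t_statistic, degrees_of_freedom = df,
                 p_value = p_value, ci = ci, conf_level = conf_level,
                 threshold = threshold, direction = direction),
            class = "cohort_test_result")
}

#' @export
print.cohort_test_result <- function(x, digits = 3, ...) {
  cat(sprintf("<cohort_test_result> %s: t(%d) = %.*f, p = %.3g (%s)\n",
              x$test, x$degrees_of_freedom, digits, x$t_statistic,
              x$p_value, x$direction))
  cat(sprintf("  estimate %.*f vs threshold %s; %g%% CI [%.*f, %.*f]\n",
              digits, x$estimate,
              if (is.na(x$threshold)) "-" else format(x$threshold),
              100 * x$conf_level, digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}
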