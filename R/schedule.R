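#' Session schedule for a monitoring day
#'
#' Describes the intended monitoring window and the cued-activity sessions
#' within it. Defaults follow the standard protocol: an 8-h window holding
#' three 30-min cued sessions with a vibrotactile cue every 30 s, i.e. 180
#' cues per day.
#'
#' All times are seconds since the start of the monitoring day. Sessions
#' must be non-overlapping and contained in the monitoring window.
#'
#' @param window_start Start of the monitoring window (s). Default 0.
#' @param window_duration Duration of the monitoring window (s). Default
#'   8 h = 28800 s.
#' @param session_starts Numeric vector of session start times (s). The
#'   default places three sessions at 1 h, 3.5 h and 6 h into the window;
#'   in the field the wearer chooses these, so they are fully configurable.
#' @param session_duration Duration of each cued session (s). Default 1800.
#' @param inter_cue_interval Seconds between consecutive cues. Default 30.
#' @return An object of class `session_schedule`.
#' @examples
#' sch <- session_schedule()
#' schedule_cue_count(sch)  # 180
#' @export
session_schedule <- function(window_start = 0,
                             window_duration = 8 * 3600,
                             session_starts = window_start + c(3600, 12600, 21600),
                             session_duration = 30 * 60,
                             inter_cue_interval = 30) {
  stopifnot(is.numeric(window_start), length(window_start) == 1L,
            is.numeric(window_duration), length(window_duration) == 1L,
            window_duration > 0,
            is.numeric(session_starts), length(session_starts) >= 1L,
            is.numeric(session_duration), session_duration > 0,
            is.numeric(inter_cue_interval), inter_cue_interval > 0)
  session_starts <- sort(as.numeric(session_starts))
  win_end <- window_start + window_duration
  if (any(session_starts < window_start) ||
      any(session_starts + session_duration > win_end))
    stop("sessions must be contained in the monitoring window")
  if (length(session_starts) > 1L &&
      any(diff(session_starts) < session_duration))
    stop("sessions must not overlap")
  structure(list(window_start = window_start,
                 window_duration = window_duration,
                 session_starts = session_starts,
                 session_duration = session_duration,
                 inter_cue_interval = inter_cue_interval),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> window [%g, %g] s (%.2f h)\n",
              x$window_start, x$window_start + x$window_duration,
              x$window_duration / 3600))
  cat(sprintf("  %d session(s) of %g min, cue every %g s (%d cues/day)\n",
              length(x$session_starts), x$session_duration / 60,
              x$inter_cue_interval, schedule_cue_count(x)))
  invisible(x)
}

#' Expected number of cues per day under a schedule
#'
#' Each session delivers `floor(session_duration / inter_cue_interval)`
#' cues; the default schedule (3 sessions of 30 min, cue every 30 s)
#' yields 180.
#'
#' @param schedule A [session_schedule()].
#' @return Integer cue count.
#' @export
schedule_cue_count <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  length(schedule$session_starts) *
    floor(schedule$session_duration / schedule$inter_cue_interval)
}

#' Nominal cue times implied by a schedule
#'
#' Cues are placed at `session_start + inter_cue_interval * (0, 1, ...)`,
#' the first cue at each session start.
#'
#' @param schedule A [session_schedule()].
#' @return Numeric vector of cue times (s), in temporal order.
#' @export
schedule_cue_times <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  per <- floor(schedule$session_duration / schedule$inter_cue_interval)
  if (per == 0L) return(numeric(0))
  as.numeric(vapply(schedule$session_starts, function(s0)
    s0 + schedule$inter_cue_interval * (seq_len(per) - 1), numeric(per)))
}

# session index (1..k) for each time, NA when outside every session
session_index_of <- function(times, schedule) {
  idx <- rep(NA_integer_, length(times))
  for (i in seq_along(schedule$session_starts)) {
    s0 <- schedule$session_starts[i]
    inside <- times >= s0 & times < s0 + schedule$session_duration
    idx[inside] <- i
  }
  idx
}
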