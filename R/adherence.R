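# Primary feasibility outcomes: wear-time compliance and cue response
# rates, plus the per-cue-index engagement curve.

#' Detect non-wear gaps in a stream
#'
#' A gap is a maximal interval inside the monitoring window with no data
#' whose duration is at least `min_gap` seconds (boundary inclusive:
#' exactly 60 s counts; 59.9 s does not). Leading and trailing intervals
#' (window start to first sample, last sample to window end) count when
#' long enough. With fewer than 2 samples, the whole window is one gap.
#'
#' @param stream An [accel_stream()], or a numeric vector of timestamps.
#' @param window `c(start, end)` of the monitoring window (s).
#' @param min_gap Minimum gap duration (s). Default 60.
#' @return Data frame with `start`, `end`, `duration` (s), possibly
#'   0 rows.
#' @examples
#' detect_gaps(c(seq(0, 30), seq(95, 200)), window = c(0, 200))
#' @export
detect_gaps <- function(stream, window, min_gap = 60) {
  t <- if (inherits(stream, "accel_stream")) stream$time else as.numeric(stream)
  t <- t[t >= window[1] & t <= window[2]]
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0))
  if (length(t) < 2L) {
    g <- data.frame(start = window[1], end = window[2],
                    duration = diff(window))
    return(if (g$duration >= min_gap) g else empty)
  }
  bounds_lo <- c(window[1], t)
  bounds_hi <- c(t, window[2])
  dur <- bounds_hi - bounds_lo
  keep <- dur >= min_gap
  if (!any(keep)) return(empty)
  data.frame(start = bounds_lo[keep], end = bounds_hi[keep],
             duration = dur[keep])
}

#' Wear-time compliance for one wrist
#'
#' Compliance is the percentage of the intended monitoring window free
#' of data gaps of at least `min_gap` seconds: the summed duration of
#' all stretches with less than `min_gap` s of consecutive missing data,
#' divided by the total monitoring time, times 100. Sub-minute holes do
#' not reduce compliance; a day with no data scores 0%.
#'
#' @param stream An [accel_stream()] (or timestamp vector).
#' @param window `c(start, end)` of the monitoring window (s); defaults
#'   to the schedule's window.
#' @param min_gap Non-wear gap rule (s). Default 60.
#' @param schedule Used only for the default window.
#' @return List of class `compliance_result`: `side`, `total_window_s`,
#'   `non_wear_s`, `compliance_pct`, and the `gaps` table.
#' @export
wear_time_compliance <- function(stream, window = NULL, min_gap = 60,
                                 schedule = session_schedule()) {
  if (is.null(window))
    window <- schedule$window_start + c(0, schedule$window_duration)
  gaps <- detect_gaps(stream, window, min_gap)
  total <- diff(window)
  non_wear <- sum(gaps$duration)
  res <- list(side = if (inherits(stream, "accel_stream")) stream$side else NA,
              total_window_s = total, non_wear_s = non_wear,
              compliance_pct = 100 * (total - non_wear) / total,
              gaps = gaps)
  stopifnot(res$compliance_pct >= 0, res$compliance_pct <= 100)
  class(res) <- "compliance_result"
  res
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf("<compliance_result> side %s: %.3f%% (%g s non-wear of %g s)\n",
              x$side, x$compliance_pct, x$non_wear_s, x$total_window_s))
  invisible(x)
}

# union of interval sets, as a (start, end) data frame
interval_union <- function(df) {
  if (nrow(df) == 0L) return(df[c("start", "end")])
  df <- df[order(df$start), ]
  st <- df$start[1L]; en <- df$end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= en) en <- max(en, df$end[i])
    else { out_s <- c(out_s, st); out_e <- c(out_e, en)
           st <- df$start[i]; en <- df$end[i] }
  }
  data.frame(start = c(out_s, st), end = c(out_e, en))
}

#' System-level wear-time compliance
#'
#' The system-level variant requires both devices simultaneously
#' connected: non-wear is the union of the two wrists' gap intervals.
#'
#' @param mi_stream,li_stream [accel_stream()] objects.
#' @inheritParams wear_time_compliance
#' @return A `compliance_result` with `side = "system"`.
#' @export
system_wear_compliance <- function(mi_stream, li_stream, window = NULL,
                                   min_gap = 60, schedule = session_schedule()) {
  if (is.null(window))
    window <- schedule$window_start + c(0, schedule$window_duration)
  g <- interval_union(rbind(detect_gaps(mi_stream, window, min_gap),
                            detect_gaps(li_stream, window, min_gap)))
  non_wear <- if (nrow(g)) sum(g$end - g$start) else 0
  total <- diff(window)
  res <- list(side = "system", total_window_s = total, non_wear_s = non_wear,
              compliance_pct = 100 * (total - non_wear) / total,
              gaps = cbind(g, duration = if (nrow(g)) g$end - g$start else numeric(0)))
  class(res) <- "compliance_result"
  res
}

in_any_interval <- function(t, df) {
  if (is.null(df) || nrow(df) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(df)))
    out <- out | (t >= df$start[i] & t < df$end[i])
  out
}

# Shared machinery for the pre-/post-cue window statistics.
# direction "post": 5 epochs starting at ceil(t_cue);
# direction "pre":  5 epochs ending at floor(t_cue).
cue_window_rate <- function(epochs, cue_log, direction, window = 5,
                            min_active = 1, gaps = NULL) {
  stopifnot(inherits(epochs, "epoch_activity"),
            inherits(cue_log, "cue_event_log"))
  if (nrow(cue_log) == 0L)
    stop("empty cue log: the rate is undefined on a silent-monitoring day")
  e0 <- epochs$epoch_start[1L]
  n_ep <- nrow(epochs)
  outcome <- character(nrow(cue_log))
  for (i in seq_len(nrow(cue_log))) {
    tc <- cue_log$time[i]
    first <- if (direction == "post") ceiling(tc) else floor(tc) - window
    idx <- (first - e0) + seq_len(window)  # 0-based offset -> 1-based rows
    if (any(idx < 1L) || any(idx > n_ep)) {
      outcome[i] <- "excluded"  # window extends past the monitoring window
      next
    }
    if (in_any_interval(tc, gaps)) {
      outcome[i] <- "excluded"  # cue fell in non-wear: no evaluable data
      next
    }
    act <- epochs$active[idx]
    outcome[i] <- if (sum(act) >= min_active) "responded" else "no_response"
  }
  delivered <- sum(outcome != "excluded")
  responded <- sum(outcome == "responded")
  list(rate = if (delivered > 0) responded / delivered else NA_real_,
       n_delivered = delivered, n_responded = responded,
       outcome = outcome, cue_index = cue_log$cue_index_in_day)
}

#' Post-cue response rate
#'
#' A cue counts as responded when it is immediately followed (within
#' `window` = 5 s) by at least `min_active` = 1 s of arm activity: at
#' least one active epoch among the 5 epochs starting at the first epoch
#' boundary at/after the cue. The rate divides responded cues by the
#' number of cues actually evaluable: cues whose window extends past the
#' monitoring window, or which fall inside a non-wear gap, are excluded
#' from numerator and denominator alike.
#'
#' @param epochs An [epoch_activity()] series for the response arm
#'   (by convention the MI wrist).
#' @param cue_log A non-empty [cue_event_log()].
#' @param window Response window length in epochs (s). Default 5.
#' @param min_active Minimum active epochs to count a response. Default 1.
#' @param gaps Optional non-wear gap table from [detect_gaps()]; cues
#'   inside these intervals are excluded.
#' @return List of class `cue_response_result`: `rate`, `n_delivered`,
#'   `n_responded`, per-cue `outcome` (`responded` / `no_response` /
#'   `excluded`) and `cue_index`.
#' @export
cue_response_rate <- function(epochs, cue_log, window = 5, min_active = 1,
                              gaps = NULL) {
  out <- cue_window_rate(epochs, cue_log, "post", window, min_active, gaps)
  class(out) <- "cue_response_result"
  out
}

#' Pre-cue activity rate
#'
#' Mirror image of [cue_response_rate()]: the fraction of cues with
#' activity in the 5 epochs ending at the last epoch boundary at/before
#' the cue. This estimates background (spontaneous) activity against
#' which the post-cue response rate is compared.
#'
#' @inheritParams cue_response_rate
#' @return List of class `cue_response_result`.
#' @export
pre_cue_activity_rate <- function(epochs, cue_log, window = 5,
                                  min_active = 1, gaps = NULL) {
  out <- cue_window_rate(epochs, cue_log, "pre", window, min_active, gaps)
  class(out) <- "cue_response_result"
  out
}

#' @export
print.cue_response_result <- function(x, ...) {
  cat(sprintf("<cue_response_result> %d/%d responded (rate %.3f), %d excluded\n",
              x$n_responded, x$n_delivered, x$rate,
              sum(x$outcome == "excluded")))
  invisible(x)
}

#' Mean response rate per within-day cue index
#'
#' Slot-wise mean response over all participant-days at each cue index
#' (1..180 under the default schedule): the engagement curve across a
#' day. Slots never delivered in any input are `NA`.
#'
#' @param results List of `cue_response_result` objects.
#' @param n_slots Number of cue slots per day. Default 180.
#' @return Data frame `cue_index`, `n_days` (days delivering that slot),
#'   `response_rate`.
#' @export
response_curve_by_cue_index <- function(results, n_slots = 180L) {
  stopifnot(length(results) >= 1L)
  num <- integer(n_slots); den <- integer(n_slots)
  for (r in results) {
    stopifnot(inherits(r, "cue_response_result"))
    keep <- r$outcome != "excluded" & r$cue_index >= 1L & r$cue_index <= n_slots
    ci <- r$cue_index[keep]
    den[ci] <- den[ci] + 1L
    num[ci] <- num[ci] + as.integer(r$outcome[keep] == "responded")
  }
  data.frame(cue_index = seq_len(n_slots), n_days = den,
             response_rate = ifelse(den > 0L, num / den, NA_real_))
}

#' Compliance and cue-response metrics for one monitoring day
#'
#' Convenience wrapper chaining [process_day()], [detect_gaps()],
#' [wear_time_compliance()] and the pre/post cue-window rates for the
#' configured response arm.
#'
#' @param day A [monitoring_day()].
#' @param config A `wristcue_config`.
#' @param signal_sides Wrists to run through the signal chain; defaults
#'   to the response side only when compliance for both sides is not
#'   needed downstream, else both.
#' @return List: `compliance` (per side + system), `rates` (`pre`,
#'   `post` `cue_response_result`s, or NULL on silent days), `epochs`.
#' @export
day_metrics <- function(day, config = load_config(),
                        signal_sides = c("MI", "LI")) {
  window <- day$schedule$window_start + c(0, day$schedule$window_duration)
  min_gap <- config$pipeline$min_gap_s
  comp <- list(
    MI = wear_time_compliance(day$mi_stream, window, min_gap),
    LI = wear_time_compliance(day$li_stream, window, min_gap),
    system = system_wear_compliance(day$mi_stream, day$li_stream, window,
                                    min_gap))
  epochs <- process_day(day, config, sides = signal_sides)
  rates <- NULL
  if (!is.null(day$cue_log) && nrow(day$cue_log) > 0L) {
    side <- config$pipeline$response_side
    if (!side %in% signal_sides) side <- signal_sides[1L]
    resp_epochs <- response_arm_epochs(epochs, side)
    gaps <- comp[[if (side %in% c("MI", "LI")) side else "system"]]$gaps
    rates <- list(
      post = cue_response_rate(resp_epochs, day$cue_log,
                               config$pipeline$response_window_s,
                               config$pipeline$min_active_s, gaps),
      pre = pre_cue_activity_rate(resp_epochs, day$cue_log,
                                  config$pipeline$response_window_s,
                                  config$pipeline$min_active_s, gaps))
  }
  list(compliance = comp, rates = rates, epochs = epochs)
}

# combine per-side epoch series according to the response-arm convention
response_arm_epochs <- function(epochs, side) {
  if (side %in% c("MI", "LI")) return(epochs[[side]])
  stopifnot(all(c("MI", "LI") %in% names(epochs)))
  mi <- epochs$MI; li <- epochs$LI
  act <- if (side == "either") mi$active | li$active else mi$active & li$active
  epoch_activity(side, mi$epoch_start, pmax(mi$magnitude_sum, li$magnitude_sum),
                 act, mi$missing & li$missing,
                 threshold = attr(mi, "threshold"))
}
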