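#' Read and write tri-axial accelerometer logs
#'
#' Logs are header + comma-delimited columns `timestamp_s, x_g, y_g, z_g`;
#' timestamps are seconds since the start of the monitoring day, stored
#' with millisecond precision (device epoch timestamps convert losslessly
#' to this convention). Unsorted rows are an error by default — sensor
#' logs should be monotone — with an opt-in `sort` flag.
#'
#' @param path File path.
#' @param side `"MI"` or `"LI"`.
#' @param sort Sort out-of-order rows instead of erroring. Default FALSE.
#' @param fs Nominal sampling rate (Hz).
#' @return [read_accel_log()]: an [accel_stream()].
#' @export
read_accel_log <- function(path, side = c("MI", "LI"), sort = FALSE,
                           fs = 12.5) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty accelerometer log: ", path)
  need <- c("timestamp_s", "x_g", "y_g", "z_g")
  if (!all(need %in% names(df)))
    stop("accelerometer log must have columns ", paste(need, collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("%s: malformed value in column %s at data line %d",
                   path, cn, bad))
    }
    df[[cn]] <- v
  }
  if (is.unsorted(df$timestamp_s, strictly = TRUE)) {
    if (!sort) {
      bad <- which(diff(df$timestamp_s) <= 0)[1L] + 1L
      stop(sprintf("%s: timestamps not strictly increasing at data line %d (t = %g); use sort = TRUE for unordered logs",
                   path, bad, df$timestamp_s[bad]))
    }
    df <- df[order(df$timestamp_s), ]
    if (any(diff(df$timestamp_s) == 0))
      stop(path, ": duplicated timestamps cannot be resolved by sorting")
  }
  accel_stream(df$timestamp_s, df$x_g, df$y_g, df$z_g, side = side, fs = fs)
}

#' @rdname read_accel_log
#' @param stream An [accel_stream()] to write.
#' @export
write_accel_log <- function(stream, path) {
  stopifnot(inherits(stream, "accel_stream"))
  df <- data.frame(timestamp_s = sprintf("%.3f", stream$time),
                   x_g = sprintf("%.6f", stream$x),
                   y_g = sprintf("%.6f", stream$y),
                   z_g = sprintf("%.6f", stream$z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cue-event logs
#'
#' A cue log is a header + one `timestamp_s` column of cue delivery
#' times. Within-day cue indices are assigned by temporal order; cues
#' outside every scheduled session are flagged (or rejected with
#' `on_outside = "error"`). An empty log denotes a silent-monitoring day.
#'
#' @param path File path.
#' @param schedule A [session_schedule()].
#' @param on_outside Passed to [cue_event_log()].
#' @return A [cue_event_log()] (possibly with 0 rows).
#' @export
read_cue_log <- function(path, schedule = session_schedule(),
                         on_outside = c("flag", "error")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp_s" %in% names(df))
    stop("cue log must have a timestamp_s column")
  ts <- suppressWarnings(as.numeric(df$timestamp_s))
  if (anyNA(ts) && nrow(df) > 0L)
    stop(sprintf("%s: malformed timestamp at data line %d", path,
                 which(is.na(ts))[1L]))
  cue_event_log(ts, schedule = schedule, on_outside = on_outside)
}

#' @rdname read_cue_log
#' @param cue_log A [cue_event_log()] to write.
#' @export
write_cue_log <- function(cue_log, path) {
  stopifnot(inherits(cue_log, "cue_event_log"))
  utils::write.csv(data.frame(timestamp_s = sprintf("%.3f", cue_log$time)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Configuration is a JSON file; absent optional keys take the defaults
#' below, and the effective configuration is echoed back by
#' [load_config()] (and can be round-tripped with [write_config()]).
#'
#' Defaults: 8-h monitoring window; three 30-min sessions starting 3600,
#' 12600 and 21600 s into the window; cue every 30 s; sampling rate
#' 12.5 Hz; band-pass 0.25-2.5 Hz; activity-count threshold 0.2 g-s per
#' epoch; non-wear gap rule >= 60 s; 5-s response window requiring >= 1 s
#' of activity; MI wrist defines a response.
#'
#' @param path JSON config file. For [load_config()], required key:
#'   `session_starts` (unless `allow_empty = TRUE`).
#' @param allow_empty If TRUE, a missing/NULL path yields the all-default
#'   config.
#' @return A list with class `wristcue_config`: components `schedule`
#'   ([session_schedule()]), `pipeline` (filter band, fs, threshold, gap
#'   and response-window parameters) and `surveys` (IMI subscale map and
#'   reverse set).
#' @export
load_config <- function(path = NULL, allow_empty = is.null(path)) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (!allow_empty) {
    stop("config path required")
  }
  if (is.null(raw$session_starts) && !allow_empty)
    stop("config must provide session_starts")
  sch <- session_schedule(
    window_start = raw$window_start %||% 0,
    window_duration = raw$window_duration %||% (8 * 3600),
    session_starts = raw$session_starts %||%
      ((raw$window_start %||% 0) + c(3600, 12600, 21600)),
    session_duration = raw$session_duration %||% 1800,
    inter_cue_interval = raw$inter_cue_interval %||% 30)
  fs <- raw$fs %||% 12.5
  band <- as.numeric(raw$band %||% c(0.25, 2.5))
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be increasing positive (low, high)")
  if (band[2] >= fs / 2)
    stop(sprintf("band upper edge %g Hz must be below the Nyquist rate %g Hz",
                 band[2], fs / 2))
  pl <- list(fs = fs, band = band,
             threshold = raw$threshold %||% 0.2,
             min_gap_s = raw$min_gap_s %||% 60,
             response_window_s = raw$response_window_s %||% 5,
             min_active_s = raw$min_active_s %||% 1,
             response_side = raw$response_side %||% "MI",
             max_interp_gap = raw$max_interp_gap %||% 2)
  if (pl$threshold <= 0) stop("threshold must be > 0")
  if (!pl$response_side %in% c("MI", "LI", "either", "both"))
    stop("response_side must be MI, LI, either or both")
  sv <- list(imi_map = raw$imi_map %||% imi_default_map(),
             imi_reverse = as.integer(raw$imi_reverse %||% imi_default_reverse()))
  structure(list(schedule = sch, pipeline = pl, surveys = sv),
            class = "wristcue_config")
}

#' @rdname load_config
#' @param config A `wristcue_config` to serialize.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "wristcue_config"))
  sch <- config$schedule
  out <- c(list(window_start = sch$window_start,
                window_duration = sch$window_duration,
                session_starts = sch$session_starts,
                session_duration = sch$session_duration,
                inter_cue_interval = sch$inter_cue_interval),
           config$pipeline,
           list(imi_map = config$surveys$imi_map,
                imi_reverse = config$surveys$imi_reverse))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write survey sheets
#'
#' A survey sheet is a CSV with one row per participant: a
#' `participant_id` column plus item columns `sus_01..sus_10`,
#' `quest_01..quest_12` (+ `quest_pick_1..3`) or `imi_01..imi_37`
#' depending on the instrument.
#'
#' @param path CSV file path.
#' @param instrument `"sus"`, `"quest"` or `"imi"`.
#' @return A data frame (validated column set); scoring is done by
#'   [score_survey_sheet()].
#' @export
read_survey_sheet <- function(path, instrument = c("sus", "quest", "imi")) {
  instrument <- match.arg(instrument)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", survey_item_cols(instrument))
  if (instrument == "quest") need <- c(need, paste0("quest_pick_", 1:3))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  df[need]
}

survey_item_cols <- function(instrument) {
  n <- c(sus = 10L, quest = 12L, imi = 37L)[[instrument]]
  sprintf("%s_%02d", instrument, seq_len(n))
}

#' Score a survey sheet
#'
#' Applies the instrument's scoring rule row-wise.
#'
#' @param sheet Data frame from [read_survey_sheet()].
#' @param instrument `"sus"`, `"quest"` or `"imi"`.
#' @param config A `wristcue_config` (supplies the IMI map).
#' @return Data frame of `participant_id` plus score column(s)
#'   (`score` for SUS/QUEST; one column per IMI subscale).
#' @export
score_survey_sheet <- function(sheet, instrument = c("sus", "quest", "imi"),
                               config = load_config()) {
  instrument <- match.arg(instrument)
  cols <- survey_item_cols(instrument)
  items <- as.matrix(sheet[cols])
  if (instrument == "sus") {
    sc <- apply(items, 1L, score_sus)
    return(data.frame(participant_id = sheet$participant_id, score = sc))
  }
  if (instrument == "quest") {
    sc <- apply(items, 1L, score_quest)
    return(data.frame(participant_id = sheet$participant_id, score = sc))
  }
  sc <- t(apply(items, 1L, score_imi,
                subscale_map = config$surveys$imi_map,
                reverse_items = config$surveys$imi_reverse))
  cbind(data.frame(participant_id = sheet$participant_id),
        as.data.frame(sc))
}

#' Write an epoch activity series pair as CSV
#'
#' Schema: `epoch_start_s, mi_sum, li_sum, mi_active, li_active,
#' mi_missing, li_missing` (activity/missing flags as 0/1).
#'
#' @param mi,li [epoch_activity()] series on the same epoch grid.
#' @param path Output file.
#' @export
write_epoch_series <- function(mi, li, path) {
  stopifnot(inherits(mi, "epoch_activity"), inherits(li, "epoch_activity"),
            nrow(mi) == nrow(li))
  df <- data.frame(epoch_start_s = mi$epoch_start,
                   mi_sum = sprintf("%.6f", mi$magnitude_sum),
                   li_sum = sprintf("%.6f", li$magnitude_sum),
                   mi_active = as.integer(mi$active),
                   li_active = as.integer(li$active),
                   mi_missing = as.integer(mi$missing),
                   li_missing = as.integer(li$missing))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
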