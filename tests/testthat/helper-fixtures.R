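# Shared fixtures and independent oracles. Everything is built in code;
# schedules are scaled down wherever the property under test does not
# depend on the full 8-h protocol.

# 10-min window, one 2-min session, cue every 30 s (4 cues)
mini_schedule <- function() {
  session_schedule(window_duration = 600, session_starts = 60,
                   session_duration = 120, inter_cue_interval = 30)
}

# 1-h window, one 30-min session (60 cues): enough cues for rate
# estimates at a fraction of the full-day cost
hour_schedule <- function() {
  session_schedule(window_duration = 3600, session_starts = 600,
                   session_duration = 1800, inter_cue_interval = 30)
}

mini_params <- function(seed, ...) generator_params(seed = seed, ...)

# epoch_activity directly from a logical activity pattern (1-Hz epochs
# starting at 0), bypassing the signal chain
flags_epochs <- function(active, start = 0, missing = rep(FALSE, length(active))) {
  epoch_activity("MI", start + seq_along(active) - 1L,
                 as.numeric(active), active & !missing, missing,
                 threshold = 1)
}

# Brute-force cue-window scan: independent of the package's
# implementation; literal loops over every (cue, epoch) pair.
oracle_window_rate <- function(active, epoch_start0, cue_times,
                               direction = "post", window = 5L,
                               min_active = 1L) {
  n <- length(active)
  delivered <- 0L; responded <- 0L
  for (tc in cue_times) {
    first <- if (direction == "post") ceiling(tc) else floor(tc) - window
    hits <- 0L; ok <- TRUE
    for (k in 0:(window - 1L)) {
      row <- (first + k) - epoch_start0 + 1L
      if (row < 1L || row > n) { ok <- FALSE; break }
      if (active[row]) hits <- hits + 1L
    }
    if (!ok) next
    delivered <- delivered + 1L
    if (hits >= min_active) responded <- responded + 1L
  }
  list(rate = if (delivered) responded / delivered else NA_real_,
       n_delivered = delivered, n_responded = responded)
}

# pooled post/pre rate estimates over several generated days
pipeline_rates <- function(params_list, schedule, config = load_config()) {
  num_post <- den_post <- num_pre <- den_pre <- 0L
  for (p in params_list) {
    day <- generate_day(p, schedule)
    ep <- process_day(day, config, sides = "MI")$MI
    post <- cue_response_rate(ep, day$cue_log)
    pre <- pre_cue_activity_rate(ep, day$cue_log)
    num_post <- num_post + post$n_responded
    den_post <- den_post + post$n_delivered
    num_pre <- num_pre + pre$n_responded
    den_pre <- den_pre + pre$n_delivered
  }
  list(post = num_post / den_post, pre = num_pre / den_pre,
       n_post = den_post, n_pre = den_pre)
}
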