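# Wear-time compliance and cue response metrics.

test_that("gap detection: boundary rule, continuity, degenerate input", {
  w <- c(0, 200)
  # continuous 1 Hz data -> no gaps
  expect_equal(nrow(detect_gaps(0:200, w)), 0L)
  # hole between 30 and 95 s: one 65-s gap (successive-difference scan)
  g <- detect_gaps(c(0:30, 95:200), w)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end, g$duration), c(30, 95, 65))
  # 59.9-s hole is below the rule; exactly 60 s counts
  expect_equal(nrow(detect_gaps(c(0:30, seq(89.9, 200, 1)), w, min_gap = 60)), 0L)
  expect_equal(nrow(detect_gaps(c(0:30, seq(90, 200, 1)), w, min_gap = 60)), 1L)
  # leading/trailing holes count too
  g2 <- detect_gaps(c(70, 71, 130), w)
  expect_equal(g2$start, c(0, 130))
  expect_equal(g2$end, c(70, 200))
  # < 2 samples: the whole window is one gap
  g3 <- detect_gaps(numeric(0), w)
  expect_equal(g3$duration, 200)
})

test_that("wear-time compliance arithmetic", {
  sch <- session_schedule()
  w <- c(0, 28800)
  t_full <- seq(0, 28800, by = 1)
  expect_equal(wear_time_compliance(t_full, w)$compliance_pct, 100)
  # one 120-s gap in 28800 s
  t_gap <- t_full[!(t_full > 10000 & t_full < 10120)]
  cr <- wear_time_compliance(t_gap, w)
  expect_equal(cr$non_wear_s, 120)
  expect_equal(cr$compliance_pct, (28800 - 120) / 28800 * 100)
  # no data at all -> 0%
  expect_equal(wear_time_compliance(numeric(0), w)$compliance_pct, 0)
})

test_that("compliance is monotone in inserted gap time; sub-minute gaps are free", {
  w <- c(0, 28800)
  t0 <- seq(0, 28800, by = 1)
  base <- wear_time_compliance(t0, w)$compliance_pct
  # inserting a 59-s gap changes nothing
  t59 <- t0[!(t0 > 500 & t0 < 559)]
  expect_equal(wear_time_compliance(t59, w)$compliance_pct, base)
  # growing gap durations never increase compliance
  last <- base
  for (dur in c(60, 120, 600, 3600)) {
    tt <- t0[!(t0 > 500 & t0 < 500 + dur)]
    cur <- wear_time_compliance(tt, w)$compliance_pct
    expect_lte(cur, last)
    last <- cur
  }
})

test_that("system compliance requires both wrists simultaneously connected", {
  w <- c(0, 1000)
  t <- seq(0, 1000)
  mi <- t[!(t > 100 & t < 200)]   # 100-s gap
  li <- t[!(t > 150 & t < 260)]   # overlapping 110-s gap
  sys <- system_wear_compliance(mi, li, w)
  expect_equal(sys$non_wear_s, 160)  # union [100, 260]
  expect_equal(sys$compliance_pct, 100 * (1000 - 160) / 1000)
})

test_that("cue response rate follows the 5-s window rule", {
  sch <- mini_schedule()
  # cues at 0, 30, 60 on a plain 0-based epoch grid
  cues <- suppressWarnings(cue_event_log(c(0, 30, 60), sch))
  active <- rep(FALSE, 600)
  active[c(3, 4)] <- TRUE   # epochs 2-3: respond to cue 1
  active[67] <- TRUE        # epoch 66: 6 s after cue 3 -> no response
  res <- cue_response_rate(flags_epochs(active), cues)
  expect_equal(res$rate, 1 / 3)
  expect_equal(res$outcome, c("responded", "no_response", "no_response"))
  # saturated and empty activity
  expect_equal(cue_response_rate(flags_epochs(rep(TRUE, 600)), cues)$rate, 1)
  expect_equal(cue_response_rate(flags_epochs(rep(FALSE, 600)), cues)$rate, 0)
  # empty cue log: undefined
  expect_error(cue_response_rate(flags_epochs(active),
                                 cue_event_log(numeric(0), sch)),
               "undefined")
})

test_that("pre-cue rate mirrors the post-cue rule", {
  sch <- mini_schedule()
  cues <- cue_event_log(c(60, 90, 120), sch)
  expect_equal(pre_cue_activity_rate(flags_epochs(rep(FALSE, 600)), cues)$rate, 0)
  expect_equal(pre_cue_activity_rate(flags_epochs(rep(TRUE, 600)), cues)$rate, 1)
  # activity in epochs 55-59 belongs to the window before the cue at 60
  active <- rep(FALSE, 600); active[56:60] <- TRUE
  expect_equal(pre_cue_activity_rate(flags_epochs(active), cues)$rate, 1 / 3)
  # but not to the post window of that cue
  expect_equal(cue_response_rate(flags_epochs(active), cues)$rate, 0)
})

test_that("cue windows extending past the monitoring window are excluded", {
  sch <- mini_schedule()
  cues <- cue_event_log(c(60, 90), sch)
  # only 70 epochs of data: cue at 90 cannot be evaluated
  res <- cue_response_rate(flags_epochs(rep(TRUE, 70)), cues)
  expect_equal(res$n_delivered, 1L)
  expect_equal(res$outcome[2], "excluded")
  expect_equal(res$rate, 1)
})

test_that("cues inside non-wear gaps drop from pre and post denominators symmetrically", {
  sch <- mini_schedule()
  cues <- cue_event_log(c(60, 90, 120, 150), sch)
  gaps <- data.frame(start = 80, end = 145, duration = 65)
  act <- rep(TRUE, 600)
  post <- cue_response_rate(flags_epochs(act), cues, gaps = gaps)
  pre <- pre_cue_activity_rate(flags_epochs(act), cues, gaps = gaps)
  expect_equal(post$n_delivered, 2L)
  expect_equal(pre$n_delivered, 2L)
  expect_equal(which(post$outcome == "excluded"),
               which(pre$outcome == "excluded"))
})

test_that("response rate matches the brute-force oracle on random instances", {
  set.seed(4711)
  sch <- mini_schedule()
  for (i in 1:60) {
    n_ep <- sample(40:120, 1)
    active <- runif(n_ep) < runif(1, 0.1, 0.9)
    n_cue <- sample(1:4, 1)
    cue_t <- sort(60 + sample(0:119, n_cue)) + round(runif(n_cue, 0, 0.9), 2)
    cue_t <- cue_t[cue_t < 60 + 120]
    if (!length(cue_t) || anyDuplicated(floor(cue_t))) next
    cues <- cue_event_log(cue_t, sch)
    for (dir in c("post", "pre")) {
      fn <- if (dir == "post") cue_response_rate else pre_cue_activity_rate
      got <- fn(flags_epochs(active), cues)
      want <- oracle_window_rate(active, 0, cue_t, dir)
      expect_equal(got$n_delivered, want$n_delivered)
      expect_equal(got$n_responded, want$n_responded)
    }
  }
})

test_that("schedule cue counts", {
  expect_equal(schedule_cue_count(session_schedule()), 180)
  expect_equal(schedule_cue_count(
    session_schedule(window_duration = 1200, session_starts = 0,
                     session_duration = 600, inter_cue_interval = 60)), 10)
  expect_equal(schedule_cue_count(
    session_schedule(window_duration = 600, session_starts = 0,
                     session_duration = 100, inter_cue_interval = 120)), 0)
})

test_that("response curve aggregates slot-wise and keeps undelivered slots missing", {
  mk_result <- function(idx, outcome) {
    structure(list(rate = mean(outcome == "responded"),
                   n_delivered = length(idx),
                   n_responded = sum(outcome == "responded"),
                   outcome = outcome, cue_index = idx),
              class = "cue_response_result")
  }
  # single day, all responded -> flat 1.0
  r1 <- mk_result(1:10, rep("responded", 10))
  c1 <- response_curve_by_cue_index(list(r1), n_slots = 12)
  expect_equal(c1$response_rate[1:10], rep(1, 10))
  expect_true(all(is.na(c1$response_rate[11:12])))
  # two days with disjoint delivered sets: union, each slot from one day
  r2 <- mk_result(11:12, c("responded", "no_response"))
  c2 <- response_curve_by_cue_index(list(r1, r2), n_slots = 12)
  expect_equal(c2$response_rate, c(rep(1, 11), 0))
  expect_equal(c2$n_days, c(rep(1L, 12)))
})

test_that("generator decay shows up as the fitted exponential slope", {
  sch <- hour_schedule()  # 60 cues/day keeps this affordable
  decay <- 0.99
  results <- list()
  cfg <- load_config()
  for (d in 1:10) {
    day <- generate_day(generator_params(seed = 5000 + d, p_post = 0.8,
                                         p_pre = 0.2,
                                         decay_per_cue = decay), sch)
    ep <- process_day(day, cfg, sides = "MI")$MI
    results[[d]] <- cue_response_rate(ep, day$cue_log)
  }
  curve <- response_curve_by_cue_index(results, n_slots = 60)
  n_days <- curve$n_days
  fit <- suppressWarnings(stats::glm(
    cbind(round(curve$response_rate * n_days),
          round((1 - curve$response_rate) * n_days)) ~ curve$cue_index,
    family = stats::binomial(link = "log")))
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  expect_lt(slope, 0)
  expect_lt(abs(slope - log(decay)), 3 * se)
})
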