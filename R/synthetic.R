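# Seeded synthetic monitoring days: gravity + sensor noise + movement
# bursts with known response/background probabilities, so the pipeline's
# estimators can be validated against ground truth.

#' Parameters of the synthetic-day generator
#'
#' The generator emulates the monitoring protocol: an 8-h day at 12.5 Hz
#' per wrist, three 30-min cued sessions with a cue every 30 s (180
#' cues/day), Bernoulli cue responses with latency under 5 s, background
#' spontaneous activity, optional within-day engagement decay, non-wear
#' gaps and connection dropouts, and distinct MI vs LI activity levels.
#' Default rates mirror the cohort the analysis targets: a 66% post-cue
#' response probability and 35% background activity per 5-s window.
#'
#' @param seed Required integer seed; identical seeds give identical
#'   output.
#' @param p_post Probability a cue elicits a response burst within 5 s.
#'   Default 0.66.
#' @param p_pre Probability an arbitrary 5-s window contains spontaneous
#'   activity. Default 0.35.
#' @param decay_per_cue Multiplicative engagement decay across the day:
#'   cue `i` responds with probability `p_post * decay^(i-1)`. Default 1.
#' @param burst_amplitude Peak acceleration of a movement burst (g).
#'   Default 0.25.
#' @param burst_duration Burst length (s), `>= 1`. Default 2.
#' @param noise_sd Resting accelerometer noise SD per axis (g). Default
#'   0.005.
#' @param gravity_vector Static gravity component (g). Default (0,0,1).
#' @param gap_spec Data frame / list of `start`, `duration` rows: non-wear
#'   gaps whose samples are excised from both wrists. Default none.
#' @param dropout_spec Same shape: short connection losses. Default none.
#' @param mi_li_activity_ratio Ratio of MI to LI background activity
#'   rates; the paretic arm moves less, so the default 0.7 makes the LI
#'   wrist's background window-activity probability `p_pre / 0.7`
#'   (capped at 1).
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(seed, p_post = 0.66, p_pre = 0.35,
                             decay_per_cue = 1, burst_amplitude = 0.25,
                             burst_duration = 2, noise_sd = 0.005,
                             gravity_vector = c(0, 0, 1),
                             gap_spec = NULL, dropout_spec = NULL,
                             mi_li_activity_ratio = 0.7) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed),
            p_post >= 0, p_post <= 1, p_pre >= 0, p_pre <= 1,
            decay_per_cue >= 0, decay_per_cue <= 1,
            burst_duration >= 1, noise_sd >= 0,
            length(gravity_vector) == 3L, mi_li_activity_ratio > 0)
  norm_spec <- function(sp) {
    if (is.null(sp)) return(data.frame(start = numeric(0), duration = numeric(0)))
    sp <- as.data.frame(sp)
    stopifnot(all(c("start", "duration") %in% names(sp)), all(sp$duration > 0))
    sp[c("start", "duration")]
  }
  structure(list(seed = as.integer(seed), p_post = p_post, p_pre = p_pre,
                 decay_per_cue = decay_per_cue,
                 burst_amplitude = burst_amplitude,
                 burst_duration = burst_duration, noise_sd = noise_sd,
                 gravity_vector = gravity_vector,
                 gap_spec = norm_spec(gap_spec),
                 dropout_spec = norm_spec(dropout_spec),
                 mi_li_activity_ratio = mi_li_activity_ratio),
            class = "generator_params")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# half-sine envelope, 1 Hz carrier: entirely inside the 0.25-2.5 Hz pass
# band, so bursts survive the filter by construction. The grid is
# uniform, so sample indices come from arithmetic, not search.
add_bursts <- function(sig, t, starts, dur, amp, fs = 12.5) {
  n <- length(sig)
  t0 <- t[1L]
  for (s in starts) {
    i0 <- max(1L, floor((s - t0) * fs) + 2L)       # first sample with t > s
    i1 <- min(n, floor((s + dur - t0) * fs) + 1L)  # last sample with t <= s+dur
    if (i1 < i0) next
    tt <- t[i0:i1] - s
    sig[i0:i1] <- sig[i0:i1] + amp * sin(pi * tt / dur) * sin(2 * pi * tt)
  }
  sig
}

#' Generate one synthetic monitoring day
#'
#' Each wrist stream is gravity + Gaussian sensor noise + movement
#' bursts on the nominal uniform grid. For cue `i` (times from the
#' schedule), with probability `p_post * decay^(i-1)` a response burst
#' starts at a uniform latency in \[0.5, 4) s after the cue on the MI
#' wrist. Background activity is a block process: each 5-s block of the
#' window independently contains a burst with probability `p_pre`
#' (`p_pre / mi_li_activity_ratio` on the LI wrist), except blocks
#' overlapping a post-cue response window, which stay clear so that the
#' post-cue and background rates remain separately identifiable.
#' Gap/dropout intervals excise samples from both wrists; response
#' bursts colliding with an excised interval are recorded as dropped in
#' the truth attribute.
#'
#' @param params A [generator_params()].
#' @param schedule A [session_schedule()].
#' @param participant_id,day_index,activity_stage Metadata.
#' @param cued Deliver cues? `FALSE` gives a silent-monitoring day.
#' @param fs Sampling rate (Hz). Default 12.5.
#' @return A [monitoring_day()] with attribute `truth`: per-cue intended
#'   response indicators and latencies, background block activity, and
#'   indices of response bursts dropped into excised gaps.
#' @examples
#' day <- generate_day(generator_params(seed = 1))
#' day
#' @export
generate_day <- function(params, schedule = session_schedule(),
                         participant_id = "P01", day_index = 1L,
                         activity_stage = "tap", cued = TRUE, fs = 12.5) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, {
    w0 <- schedule$window_start
    n <- round(schedule$window_duration * fs)
    t <- w0 + (seq_len(n) - 1L) / fs
    g <- params$gravity_vector
    mk_noise <- function() list(x = g[1] + rnorm(n, 0, params$noise_sd),
                                y = g[2] + rnorm(n, 0, params$noise_sd),
                                z = g[3] + rnorm(n, 0, params$noise_sd))
    mi <- mk_noise(); li <- mk_noise()

    cue_times <- if (cued) schedule_cue_times(schedule) else numeric(0)
    n_cue <- length(cue_times)
    respond <- logical(0); latency <- numeric(0)
    if (n_cue) {
      p_i <- params$p_post * params$decay_per_cue^(seq_len(n_cue) - 1L)
      respond <- runif(n_cue) < p_i
      latency <- runif(n_cue, 0.5, 4)
      mi$x <- add_bursts(mi$x, t, cue_times[respond] + latency[respond],
                         params$burst_duration, params$burst_amplitude)
    }

    # background: one candidate burst per 5-s block, kept clear of every
    # post-cue response window
    block_len <- 5
    n_block <- floor(schedule$window_duration / block_len)
    block_start <- w0 + block_len * (seq_len(n_block) - 1L)
    post_blocked <- block_start %in% (block_len * floor(cue_times / block_len))
    margin <- 0.3  # keeps filter ringing inside the block
    place_background <- function(sig, prob) {
      on_blocks <- runif(n_block) < prob & !post_blocked
      if (!any(on_blocks)) return(list(sig = sig, blocks = on_blocks))
      span <- block_len - params$burst_duration - 2 * margin
      stopifnot(span > 0)
      starts <- block_start[on_blocks] + margin + runif(sum(on_blocks), 0, span)
      list(sig = add_bursts(sig, t, starts, params$burst_duration,
                            params$burst_amplitude),
           blocks = on_blocks)
    }
    bg_mi <- place_background(mi$x, params$p_pre)
    mi$x <- bg_mi$sig
    bg_li <- place_background(li$x, min(1, params$p_pre / params$mi_li_activity_ratio))
    li$x <- bg_li$sig

    # excise samples inside gaps and dropouts (both wrists)
    excised <- rbind(params$gap_spec, params$dropout_spec)
    keep <- rep(TRUE, n)
    if (nrow(excised))
      for (i in seq_len(nrow(excised)))
        keep <- keep & !(t >= excised$start[i] &
                         t < excised$start[i] + excised$duration[i])
    dropped <- integer(0)
    if (n_cue && nrow(excised)) {
      b0 <- cue_times + latency
      for (i in seq_len(nrow(excised))) {
        hit <- respond & b0 < excised$start[i] + excised$duration[i] &
          (b0 + params$burst_duration) > excised$start[i]
        dropped <- union(dropped, which(hit))
      }
    }

    # quantize to log precision (ms timestamps, micro-g accelerations) so
    # written fixtures read back bit-identical
    tq <- round(t[keep], 3)
    mi_stream <- accel_stream(tq, round(mi$x[keep], 6), round(mi$y[keep], 6),
                              round(mi$z[keep], 6), side = "MI", fs = fs)
    li_stream <- accel_stream(tq, round(li$x[keep], 6), round(li$y[keep], 6),
                              round(li$z[keep], 6), side = "LI", fs = fs)
    cue_log <- if (n_cue) cue_event_log(cue_times, schedule) else NULL
    day <- monitoring_day(participant_id, day_index, schedule,
                          mi_stream, li_stream, cue_log, activity_stage)
    attr(day, "truth") <- list(respond = respond, latency = latency,
                               background_blocks_mi = bg_mi$blocks,
                               background_blocks_li = bg_li$blocks,
                               dropped_response_bursts = sort(dropped))
    day
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-participant response parameters reproducibly from truncated
#' normal distributions, generates `n_days` monitoring days per
#' participant, and (optionally) paired survey sheets from configurable
#' item distributions. All randomness flows from `seed`; two calls with
#' the same arguments are identical.
#'
#' @param n_participants Number of participants, `>= 1`.
#' @param seed Integer master seed.
#' @param n_days Monitoring days per participant. Default 3.
#' @param params_distribution List with elements `p_post = c(mean, sd)`
#'   and `p_pre = c(mean, sd)`; per-participant probabilities are drawn
#'   from these normals truncated to \[0, 1\]. Defaults mirror the target
#'   cohort: post 0.66 +/- 0.2245, pre 0.3481 +/- 0.1412.
#' @param base_params A [generator_params()] used as a template for the
#'   non-probability settings (its seed and probabilities are replaced).
#' @param schedule A [session_schedule()].
#' @param surveys Also draw SUS/QUEST/IMI sheets? Default TRUE.
#' @return List of class `synthetic_cohort`: `participants` (each with
#'   `participant_id`, `p_post`, `p_pre`, `days` = list of
#'   [monitoring_day()]), `surveys` (data frames `sus`, `quest`, `imi`),
#'   and `seed`.
#' @export
generate_cohort <- function(n_participants, seed, n_days = 3L,
                            params_distribution = list(
                              p_post = c(0.66, 0.2245),
                              p_pre = c(0.3481, 0.1412)),
                            base_params = generator_params(seed = 0L),
                            schedule = session_schedule(),
                            surveys = TRUE) {
  if (n_participants < 1L) stop("n_participants must be >= 1")
  with_seed(seed, {
    rtrunc01 <- function(n, ms) pmin(1, pmax(0, rnorm(n, ms[1], ms[2])))
    p_post <- rtrunc01(n_participants, params_distribution$p_post)
    p_pre <- rtrunc01(n_participants, params_distribution$p_pre)
    day_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_participants * n_days),
                        nrow = n_participants)
    latent <- rnorm(n_participants)  # shared person-level quality trait
    participants <- lapply(seq_len(n_participants), function(i) {
      pid <- sprintf("P%02d", i)
      days <- lapply(seq_len(n_days), function(d) {
        pp <- base_params
        pp$seed <- day_seeds[i, d]
        pp$p_post <- p_post[i]
        pp$p_pre <- p_pre[i]
        generate_day(pp, schedule, participant_id = pid, day_index = d,
                     activity_stage = c("tap", "assist", "independent")[
                       pmin(d, 3L)])
      })
      list(participant_id = pid, p_post = p_post[i], p_pre = p_pre[i],
           days = days)
    })
    sheets <- if (surveys) draw_survey_sheets(n_participants, latent) else NULL
    structure(list(participants = participants, surveys = sheets,
                   seed = seed),
              class = "synthetic_cohort")
  })
}

# Item-level survey draws around a person-level latent trait. Targets
# (documented in the methods vignette) approximate the cohort means the
# analysis reports on: SUS ~ 80, QUEST ~ 4.5, IMI subscales 4.9-6.2 with
# pressure/tension low (~2.8).
draw_survey_sheets <- function(n, latent) {
  clamp <- function(x, lo, hi) as.integer(pmin(hi, pmax(lo, round(x))))
  sus <- matrix(0L, n, 10L)
  for (j in 1:10) {
    pos <- j %% 2L == 1L
    base <- if (pos) 4.2 else 1.8
    slope <- if (pos) 0.5 else -0.5
    sus[, j] <- clamp(base + slope * latent + rnorm(n, 0, 0.7), 1L, 5L)
  }
  quest <- matrix(0L, n, 12L)
  for (j in 1:12)
    quest[, j] <- clamp(4.5 + 0.4 * latent + rnorm(n, 0, 0.5), 1L, 5L)
  labels <- quest_item_labels()
  pick_w <- stats::setNames(rep(1, 12), labels)
  pick_w[c("ease_of_use", "comfort", "effectiveness")] <- 6
  pick_w[c("troubleshooting", "dimensions")] <- 0.3
  picks <- t(vapply(seq_len(n), function(i)
    sample(labels, 3L, prob = pick_w), character(3)))
  targets <- c(interest_enjoyment = 4.9, effort_importance = 5.4,
               value_usefulness = 6.2, perceived_choice = 6.0,
               perceived_competence = 5.8, pressure_tension = 2.8)
  map <- imi_default_map(); rev_items <- imi_default_reverse()
  imi <- matrix(0L, n, 37L)
  for (j in 1:37) {
    mu <- targets[[map[j]]]
    sgn <- if (map[j] == "pressure_tension") -0.8 else 0.8
    val <- clamp(mu + sgn * latent + rnorm(n, 0, 0.8), 1L, 7L)
    imi[, j] <- if (j %in% rev_items) 8L - val else val
  }
  pid <- sprintf("P%02d", seq_len(n))
  sus_df <- data.frame(participant_id = pid, sus)
  names(sus_df)[-1L] <- survey_item_cols("sus")
  quest_df <- data.frame(participant_id = pid, quest,
                         quest_pick_1 = picks[, 1L],
                         quest_pick_2 = picks[, 2L],
                         quest_pick_3 = picks[, 3L])
  names(quest_df)[2:13] <- survey_item_cols("quest")
  imi_df <- data.frame(participant_id = pid, imi)
  names(imi_df)[-1L] <- survey_item_cols("imi")
  list(sus = sus_df, quest = quest_df, imi = imi_df)
}

#' Write a synthetic cohort as a fixture directory
#'
#' Lays out a full plain-text fixture: per participant-day accelerometer
#' and cue logs (`<id>/day<k>/accel_MI.csv`, `accel_LI.csv`,
#' `cues.csv`), survey sheets under `surveys/`, and a `manifest.json`
#' recording the generating parameters.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config A `wristcue_config` serialized alongside the data.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(cohort, dir, config = load_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    for (day in p$days) {
      dd <- file.path(dir, p$participant_id, sprintf("day%d", day$day_index))
      dir.create(dd, recursive = TRUE, showWarnings = FALSE)
      write_accel_log(day$mi_stream, file.path(dd, "accel_MI.csv"))
      write_accel_log(day$li_stream, file.path(dd, "accel_LI.csv"))
      if (!is.null(day$cue_log))
        write_cue_log(day$cue_log, file.path(dd, "cues.csv"))
    }
  }
  if (!is.null(cohort$surveys)) {
    sd <- file.path(dir, "surveys")
    dir.create(sd, showWarnings = FALSE)
    for (nm in names(cohort$surveys))
      utils::write.csv(cohort$surveys[[nm]],
                       file.path(sd, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  write_config(config, file.path(dir, "config.json"))
  manifest <- list(
    seed = cohort$seed,
    n_participants = length(cohort$participants),
    n_days = length(cohort$participants[[1L]]$days),
    participants = lapply(cohort$participants, function(p)
      list(participant_id = p$participant_id, p_post = p$p_post,
           p_pre = p$p_pre)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
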