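# Cohort aggregation and report generation: per-day metrics ->
# per-participant averages -> cohort tests -> machine-readable JSON plus
# a human-readable text summary.

#' Compute per-day metrics over a cohort
#'
#' Runs [day_metrics()] on every monitoring day of a cohort (either a
#' `synthetic_cohort` or a plain list of participants, each a list with
#' `participant_id` and `days`).
#'
#' @param cohort A `synthetic_cohort` or compatible list.
#' @param config A `wristcue_config`.
#' @param signal_sides Passed to [day_metrics()].
#' @return List of class `cohort_metrics`: `compliance` (long data
#'   frame: participant, day, side, compliance_pct), `rates` (data
#'   frame: participant, day, pre_rate, post_rate, n_cues) and
#'   `cue_results` (list of per-day `cue_response_result`s, for the
#'   engagement curve).
#' @export
cohort_metrics <- function(cohort, config = load_config(),
                           signal_sides = c("MI", "LI")) {
  participants <- if (inherits(cohort, "synthetic_cohort"))
    cohort$participants else cohort
  comp <- list(); rates <- list(); cue_results <- list()
  for (p in participants) {
    for (day in p$days) {
      dm <- day_metrics(day, config, signal_sides = signal_sides)
      for (sd_ in names(dm$compliance))
        comp[[length(comp) + 1L]] <- data.frame(
          participant = p$participant_id, day = day$day_index, side = sd_,
          compliance_pct = dm$compliance[[sd_]]$compliance_pct)
      if (!is.null(dm$rates)) {
        rates[[length(rates) + 1L]] <- data.frame(
          participant = p$participant_id, day = day$day_index,
          pre_rate = dm$rates$pre$rate, post_rate = dm$rates$post$rate,
          n_cues = dm$rates$post$n_delivered)
        cue_results[[length(cue_results) + 1L]] <- dm$rates$post
      }
    }
  }
  structure(list(compliance = do.call(rbind, comp),
                 rates = if (length(rates)) do.call(rbind, rates),
                 cue_results = cue_results),
            class = "cohort_metrics")
}

# per-participant averages of daily values (cohort statistics are then
# taken over participants, matching the study's aggregation order)
participant_means <- function(df, value_cols) {
  out <- stats::aggregate(df[value_cols], by = list(participant = df$participant),
                          FUN = base::mean)
  out[order(out$participant), , drop = FALSE]
}

mean_sd <- function(x) {
  x <- x[!is.na(x)]
  list(mean = base::mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA,
       n = length(x))
}

test_or_null <- function(values, ...) {
  values <- values[!is.na(values)]
  if (length(values) < 2L || stats::sd(values) == 0) return(NULL)
  one_sample_t(values = values, ...)
}

tidy_test <- function(tst) {
  if (is.null(tst)) return(NULL)
  list(t = tst$t_statistic, df = tst$degrees_of_freedom, p = tst$p_value,
       estimate = tst$estimate, ci = tst$ci, conf_level = tst$conf_level,
       threshold = tst$threshold, direction = tst$direction)
}

#' Build a cohort feasibility report
#'
#' Assembles the phase-level summary: mean +/- sd wear-time compliance
#' per side with the one-sided test against the 90% minimum; pre/post
#' cue rates with the paired test and the one-sided response-rate test
#' against 90%; survey scores against their passability thresholds (SUS
#' 68; QUEST reported against both the stated midpoint 3 and the
#' alternative 4, a documented reporting discrepancy; IMI subscales
#' against 4, pressure/tension one-sided low); the QUEST importance
#' tally; and the 180-slot engagement curve. Cohort tests are suppressed
#' (not fabricated) when fewer than 2 participants contribute; absent
#' inputs yield absent sections.
#'
#' @param metrics A `cohort_metrics` (or NULL).
#' @param surveys List with optional data frames `sus`, `quest`, `imi`
#'   (item-level sheets) or NULL.
#' @param config A `wristcue_config`.
#' @param phase Label, e.g. `"IRF"` or `"home"`.
#' @param wear_threshold_pct Compliance/response threshold. Default 90.
#' @return List of class `cohort_report` (JSON-ready).
#' @export
cohort_report <- function(metrics = NULL, surveys = NULL,
                          config = load_config(), phase = "IRF",
                          wear_threshold_pct = 90) {
  if (is.null(metrics) && is.null(surveys))
    stop("at least one of metrics or surveys is required")
  rep_ <- list(phase = phase)

  if (!is.null(metrics)) {
    comp <- metrics$compliance
    comp_sec <- list()
    for (sd_ in unique(comp$side)) {
      pm <- participant_means(comp[comp$side == sd_, ], "compliance_pct")
      comp_sec[[sd_]] <- c(mean_sd(pm$compliance_pct),
                           list(test_vs_threshold = tidy_test(
                             test_or_null(pm$compliance_pct,
                                          threshold = wear_threshold_pct,
                                          direction = "greater",
                                          conf_level = 0.90))))
    }
    rep_$compliance <- comp_sec

    if (!is.null(metrics$rates) && nrow(metrics$rates)) {
      pm <- participant_means(metrics$rates, c("pre_rate", "post_rate"))
      paired <- if (nrow(pm) >= 2L &&
                    stats::sd(pm$post_rate - pm$pre_rate) > 0)
        paired_t(pm$pre_rate, pm$post_rate)
      rep_$cue_response <- list(
        post = mean_sd(100 * pm$post_rate),
        pre = mean_sd(100 * pm$pre_rate),
        paired_test_pct = tidy_test(
          if (!is.null(paired)) {
            paired$estimate <- 100 * paired$estimate
            paired$ci <- 100 * paired$ci
            paired
          }),
        response_vs_threshold = tidy_test(
          test_or_null(100 * pm$post_rate, threshold = wear_threshold_pct,
                       direction = "greater", conf_level = 0.90)))
      curve <- response_curve_by_cue_index(metrics$cue_results)
      rep_$response_curve <- list(cue_index = curve$cue_index,
                                  n_days = curve$n_days,
                                  response_rate = curve$response_rate)
    } else {
      rep_$cue_response <- list(absent = TRUE,
                                note = "silent monitoring: no cues delivered")
    }
  }

  if (!is.null(surveys)) {
    sv <- list()
    if (!is.null(surveys$sus)) {
      sc <- score_survey_sheet(surveys$sus, "sus", config)$score
      sv$sus <- c(mean_sd(sc), list(test_vs_68 = tidy_test(
        test_or_null(sc, threshold = 68, direction = "greater",
                     conf_level = 0.90))))
    }
    if (!is.null(surveys$quest)) {
      sc <- score_survey_sheet(surveys$quest, "quest", config)$score
      picks <- lapply(seq_len(nrow(surveys$quest)), function(i)
        as.character(surveys$quest[i, paste0("quest_pick_", 1:3)]))
      sv$quest <- c(mean_sd(sc), list(
        test_vs_3 = tidy_test(test_or_null(sc, threshold = 3,
                                           direction = "greater",
                                           conf_level = 0.90)),
        test_vs_4 = tidy_test(test_or_null(sc, threshold = 4,
                                           direction = "greater",
                                           conf_level = 0.90)),
        importance_tally = as.list(quest_importance_tally(picks))))
    }
    if (!is.null(surveys$imi)) {
      sc <- score_survey_sheet(surveys$imi, "imi", config)
      sub <- setdiff(names(sc), "participant_id")
      sv$imi <- lapply(stats::setNames(sub, sub), function(s)
        c(mean_sd(sc[[s]]), list(test_vs_4 = tidy_test(
          test_or_null(sc[[s]], threshold = 4,
                       direction = if (s == "pressure_tension") "less"
                                   else "greater",
                       conf_level = 0.90)))))
    }
    rep_$surveys <- sv
  }
  class(rep_) <- c("cohort_report", "list")
  rep_
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (machine-readable, deterministic for identical
#' inputs) and `report.txt` (human-readable summary).
#'
#' @param report A `cohort_report`.
#' @param out_dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(out_dir, "report.json")
  unclass_report <- unclass(report)
  jsonlite::write_json(unclass_report, jpath, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  tpath <- file.path(out_dir, "report.txt")
  con <- file(tpath, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Cohort feasibility report - phase: %s", report$phase)
  fmt_t <- function(tst, label) {
    if (is.null(tst)) return(sprintf("  %s: suppressed (n < 2)", label))
    sprintf("  %s: t(%d) = %.2f, p = %.3g, %g%% CI [%.2f, %.2f]",
            label, tst$df, tst$t, tst$p, 100 * tst$conf_level,
            tst$ci[1], tst$ci[2])
  }
  if (!is.null(report$compliance)) {
    w("Wear-time compliance (%% of intended window):")
    for (sd_ in names(report$compliance)) {
      s <- report$compliance[[sd_]]
      w("  %s: %.1f +/- %.1f%% (n = %d)", sd_, s$mean,
        if (is.na(s$sd)) NA else s$sd, s$n)
      w("%s", fmt_t(s$test_vs_threshold, "vs 90%"))
    }
  }
  if (!is.null(report$cue_response) && is.null(report$cue_response$absent)) {
    cr <- report$cue_response
    w("Cue response rates (%%):")
    w("  post-cue: %.2f +/- %.2f; pre-cue: %.2f +/- %.2f (n = %d)",
      cr$post$mean, cr$post$sd, cr$pre$mean, cr$pre$sd, cr$post$n)
    w("%s", fmt_t(cr$paired_test_pct, "paired post - pre"))
    w("%s", fmt_t(cr$response_vs_threshold, "post vs 90%"))
  }
  if (!is.null(report$surveys)) {
    sv <- report$surveys
    if (!is.null(sv$sus)) {
      w("SUS: %.1f +/- %.1f (n = %d)", sv$sus$mean, sv$sus$sd, sv$sus$n)
      w("%s", fmt_t(sv$sus$test_vs_68, "vs 68"))
    }
    if (!is.null(sv$quest)) {
      w("QUEST: %.2f +/- %.2f (n = %d)", sv$quest$mean, sv$quest$sd,
        sv$quest$n)
      w("%s", fmt_t(sv$quest$test_vs_3, "vs 3 (stated midpoint)"))
      w("%s", fmt_t(sv$quest$test_vs_4, "vs 4 (alternative)"))
    }
    if (!is.null(sv$imi)) {
      w("IMI subscales:")
      for (s in names(sv$imi)) {
        x <- sv$imi[[s]]
        w("  %s: %.2f +/- %.2f", s, x$mean, x$sd)
        w("%s", fmt_t(x$test_vs_4, "  vs 4"))
      }
    }
  }
  invisible(c(json = jpath, txt = tpath))
}
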