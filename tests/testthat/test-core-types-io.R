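# Domain types, readers/writers, configuration.

test_that("accel_stream enforces its invariants", {
  s <- accel_stream(c(0, 0.08, 0.16), c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), "MI")
  expect_s3_class(s, "accel_stream")
  expect_error(accel_stream(c(0, 0.08, 0.08), 1:3, 1:3, 1:3, "MI"),
               "strictly increasing")
  expect_error(accel_stream(c(0, 0.08), c(0, Inf), c(0, 0), c(1, 1), "MI"),
               "finite")
  expect_error(accel_stream(c(0, 0.08), 0, c(0, 0), c(1, 1), "MI"),
               "equal length")
})

test_that("accelerometer log read is an identity on well-formed files and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,x_g,y_g,z_g",
               "0.000,0.010000,-0.020000,0.980000",
               "0.080,0.011000,-0.019000,0.981000",
               "0.160,0.012000,-0.021000,0.979000",
               "0.240,0.010000,-0.020000,0.980000"), path)
  s <- read_accel_log(path, "MI")
  expect_length(s$time, 4L)
  expect_equal(s$x, c(0.010, 0.011, 0.012, 0.010))

  writeLines(c("timestamp_s,x_g,y_g,z_g",
               "0.000,0,0,1", "0.080,0,0,1", "0.080,0,0,1"), path)
  expect_error(read_accel_log(path, "MI"), "line 3")

  writeLines(c("timestamp_s,x_g,y_g,z_g", "0.000,zero,0,1"), path)
  expect_error(read_accel_log(path, "MI"), "malformed")

  writeLines("timestamp_s,x_g,y_g,z_g", path)
  expect_error(read_accel_log(path, "MI"), "empty")
})

test_that("unsorted rows error by default and sort on request", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,x_g,y_g,z_g",
               "0.080,1,0,0", "0.000,2,0,0"), path)
  expect_error(read_accel_log(path, "MI"), "sort = TRUE")
  s <- read_accel_log(path, "MI", sort = TRUE)
  expect_equal(s$x, c(2, 1))
})

test_that("write -> read round trip is the identity for generated streams", {
  day <- generate_day(mini_params(11), mini_schedule())
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel_log(day$mi_stream, path)
  back <- read_accel_log(path, "MI")
  expect_identical(back$time, day$mi_stream$time)
  # values agree at full storage precision (1 ulp: round() and the
  # decimal serialization may pick adjacent doubles)
  expect_equal(back$x, day$mi_stream$x, tolerance = 1e-12)
  expect_equal(back$z, day$mi_stream$z, tolerance = 1e-12)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_cue_log(day$cue_log, cpath)
  back_cues <- read_cue_log(cpath, mini_schedule())
  expect_identical(back_cues$time, day$cue_log$time)
  expect_identical(back_cues$cue_index_in_day, day$cue_log$cue_index_in_day)
})

test_that("cue logs validate count, order and session membership", {
  sch <- session_schedule()
  full <- schedule_cue_times(sch)
  log <- cue_event_log(full, sch)
  expect_equal(nrow(log), 180L)
  expect_equal(log$cue_index_in_day, 1:180)
  expect_true(all(log$in_session))
  expect_error(cue_event_log(c(full, 23500), sch), "exceed")
  expect_error(cue_event_log(c(10, 10), sch), "strictly increasing")
  # a cue between sessions is flagged, or rejected on request
  expect_warning(l2 <- cue_event_log(7000, sch), "outside")
  expect_false(l2$in_session)
  expect_error(cue_event_log(7000, sch, on_outside = "error"), "outside")
  # empty log: a silent-monitoring day
  e <- cue_event_log(numeric(0), sch)
  expect_equal(nrow(e), 0L)
})

test_that("empty cue file reads as a silent-monitoring log", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp_s", path)
  expect_equal(nrow(read_cue_log(path, session_schedule())), 0L)
})

test_that("monitoring_day construction fails loudly on invariant violations", {
  sch <- mini_schedule()
  day <- generate_day(mini_params(5), sch)
  expect_s3_class(day, "monitoring_day")
  # cue outside sessions cannot enter a monitoring day
  suppressWarnings(bad_log <- cue_event_log(10, sch))
  expect_error(monitoring_day("P", 1, sch, day$mi_stream, day$li_stream,
                              bad_log), "inside scheduled sessions")
  expect_error(monitoring_day("P", 1, sch, day$li_stream, day$mi_stream),
               "side")
  expect_error(monitoring_day("P", 1, sch, day$mi_stream, day$li_stream,
                              activity_stage = "resting"), "activity_stage")
})

test_that("config defaults, validation and round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"session_starts": [3600, 12600, 21600]}', path)
  cfg <- load_config(path)
  expect_equal(cfg$schedule$window_duration, 8 * 3600)
  expect_equal(cfg$schedule$session_duration, 1800)
  expect_equal(cfg$schedule$inter_cue_interval, 30)
  expect_equal(cfg$pipeline$band, c(0.25, 2.5))
  expect_equal(cfg$pipeline$fs, 12.5)

  writeLines('{"session_starts": [3600], "band": [0.25, 7]}', path)
  expect_error(load_config(path), "Nyquist")
  writeLines('{"window_duration": 600}', path)
  expect_error(load_config(path), "session_starts")

  cfg <- load_config()
  out <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, out)
  cfg2 <- load_config(out)
  expect_equal(cfg2$schedule, cfg$schedule)
  expect_equal(cfg2$pipeline, cfg$pipeline)
  expect_equal(cfg2$surveys, cfg$surveys)
})

test_that("survey sheets round trip through CSV", {
  cohort <- generate_cohort(3, seed = 9, n_days = 1, schedule = mini_schedule())
  dir <- withr::local_tempdir()
  write_fixture_dir(cohort, dir)
  sus <- read_survey_sheet(file.path(dir, "surveys", "sus.csv"), "sus")
  expect_equal(nrow(sus), 3L)
  expect_identical(sus, cohort$surveys$sus)
  expect_error(read_survey_sheet(file.path(dir, "surveys", "sus.csv"),
                                 "quest"), "missing column")
})
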