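Package: wristcue
Title: Dual-Wrist Accelerometry Analysis for Vibrotactile Cued-Activity Programs
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wrist-worn accelerometer studies of
    vibrotactile cued-activity programs in rehabilitation. Reads dual-wrist
    tri-axial accelerometer logs (nominal 12.5 Hz, units of g) and cue-event
    logs; synchronizes and resamples the two wrists onto a common grid;
    band-pass filters each axis (0.25-2.5 Hz, zero phase) to remove gravity;
    forms per-second epoch sums of the Euclidean acceleration magnitude and
    thresholds them into binary activity counts; detects non-wear gaps
    (>= 60 s) and computes wear-time compliance; computes post-cue response
    rates and pre-cue activity rates over 5-s windows; scores SUS, QUEST and
    IMI user-experience surveys; and reports cohort-level one-sided threshold
    t-tests and the paired pre/post comparison. A seeded synthetic-data
    generator emulates the monitoring protocol (8-h window, three 30-min
    sessions, cues every 30 s) so the full pipeline is testable without raw
    device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
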