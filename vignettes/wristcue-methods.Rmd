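---
title: "Methods: from dual-wrist accelerometry to cued-activity outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dual-wrist accelerometry to cued-activity outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wristcue)
```

## The measurement problem

Wrist-worn cueing systems for stroke rehabilitation deliver a
vibrotactile prompt on a fixed schedule — here, every 30 s within three
30-min sessions of an 8-h monitoring day, 180 cues in total — and use
the devices' accelerometers to decide, cue by cue, whether the wearer
responded with arm movement. Three quantities carry the feasibility
argument:

* **wear-time compliance**: the fraction of the intended window with
  usable data from the devices;
* the **post-cue response rate**: the fraction of delivered cues
  followed within 5 s by at least 1 s of arm activity;
* the **pre-cue activity rate**: the same statistic computed on the 5 s
  *before* each cue. This is the natural control: if cues do nothing,
  post- and pre-cue rates coincide, so the paired difference across
  participants is the efficacy signal.

User experience is measured by three standard instruments (SUS, QUEST,
IMI) scored against conventional cut-offs.

## Signal model and curation chain

Each wrist produces time-stamped tri-axial samples in units of g at a
nominal 12.5 Hz. The curation chain is:

1. **Synchronize/resample.** Both wrists are mapped onto the uniform
   12.5 Hz grid spanning the monitoring window by linear interpolation
   between neighbouring samples. Interpolation is trusted only between
   samples at most 2 nominal intervals (0.16 s) apart; grid points
   inside larger holes are *missing*, never painted over — holes carry
   the wear-time meaning.
2. **Band-pass filter, 0.25–2.5 Hz.** The static gravity component and
   sub-0.25 Hz drift carry no movement information, and the band's
   upper edge rejects high-frequency noise. The filter is a 4th-order
   Butterworth applied forward–backward (zero phase), so cue–response
   latencies are not shifted by filter delay. The generic band-pass
   routine this emulates does not pin order or phase handling; both are
   parameterized, and the defaults are recorded in the configuration.
   Filtering is applied independently to each contiguous run of
   observed samples. Runs shorter than three settling lengths of the
   low band edge (3 × `fs`/0.25 Hz = 150 samples, 12 s) are dominated by
   edge transients and are marked missing rather than filtered.
   Forward–backward passes use odd-reflection padding of the same
   length, which also makes the output exactly invariant (to numerical
   precision) under constant axis offsets.
3. **Magnitude and epoching.** The per-sample Euclidean norm is summed
   within 1-s epochs. Epochs are half-open and 0-based: epoch *k*
   covers [*k*, *k*+1) seconds, containing 12 or 13 samples depending
   on grid phase. Epochs with ≥ 50% missing samples are missing.
4. **Activity counts.** Epoch *k* is *active* iff its magnitude sum is
   ≥ θ (boundary inclusive). Missing epochs count as inactive but stay
   flagged, so true zeros and absent data remain distinguishable.

**The threshold θ** (default 0.2 g·s per epoch) is a calibrated
constant: at the generator's default resting noise (σ = 5 mg per axis)
the largest resting epoch sum over a full day is ≈ 0.12 g·s, so the
false-active rate at rest is far below the 1% design target, while a
default movement burst (0.25 g peak) contributes epoch sums an order of
magnitude above θ. The source analysis names a thresholding approach
but prints no value; θ is configuration, echoed into every output
manifest, and comparisons across datasets must hold it fixed.

## Window conventions

The source analysis does not define the phase relation between cues and
epochs; the package fixes deterministic, symmetric conventions:

* post-cue window: the 5 epochs starting at `ceiling(t_cue)`;
* pre-cue window: the 5 epochs ending at `floor(t_cue)`;
* "a period of activity ≥ 1 s" means ≥ 1 active epoch in the window —
  at 1-s resolution a 1-s period is exactly one epoch, and contiguity
  is not imposed.

A cue is *excluded from numerator and denominator alike* when its
window extends past the monitoring window or when the cue falls inside
a detected non-wear gap: the "number of cues actually provided" cannot
be evaluated without data. Because exclusion is keyed on the cue
timestamp, doffing both devices shrinks pre- and post-cue denominators
symmetrically and does not bias their comparison. Which arm counts as
the response arm is likewise unstated in the field's reports; the
default is the more-involved wrist (the program targets MI engagement),
configurable to either-wrist or both-wrist conjunction.

## Non-wear and compliance

A gap is a maximal data-free interval of duration ≥ 60 s (boundary
inclusive: exactly 60 s counts, 59.9 s does not), including leading and
trailing intervals of the window; with fewer than two samples the whole
window is one gap. Compliance is `100 × (window − Σ gaps)/window`.
Sub-minute holes are free by definition, so compliance is monotone
non-increasing in inserted gap time only once gaps cross the rule. The
system-level variant takes the union of both wrists' gap intervals
(both devices simultaneously connected). Estimating non-wear while the
devices remain connected (doffed but in proximity) is explicitly out of
scope, mirroring the source analysis.

## The synthetic-data generator as a stated world

`generate_day()` produces one monitoring day per seed:

* per axis: gravity (default (0, 0, 1) g) + Gaussian sensor noise
  (default σ = 5 mg, a realistic MEMS accelerometer figure at this
  rate);
* for cue *i*, with probability `p_post · decay^(i−1)` a movement burst
  starts at a uniform latency in [0.5, 4) s after the cue on the MI
  wrist. The latency floor keeps the burst inside the 5-s window after
  epoch quantization; the ceiling plus the 2-s default duration
  guarantees at least one fully covered epoch inside the window, so an
  intended response is always detectable;
* background activity is a block process: each 5-s block of the window
  independently receives a burst with probability `p_pre` (LI wrist:
  `p_pre / mi_li_activity_ratio`, capped at 1; the default ratio 0.7
  makes the non-paretic arm more active). Bursts sit 0.3 s inside their
  block so filter ringing cannot leak across block boundaries;
* bursts are half-sine envelopes on a 1-Hz carrier — inside the pass
  band by construction. No claim is made that real paretic-arm movement
  has this spectrum; the carrier is a modeling convention chosen so the
  filter cannot destroy what the generator asserts exists;
* gap/dropout intervals excise samples from both wrists; response
  bursts colliding with an excised interval are recorded as dropped in
  the truth attribute.

Default rates are the cohort figures the analysis targets: `p_post =
0.66`, `p_pre = 0.35`. Defaults were fixed before the test suite was
run and are not tuned.

**Identifiability.** Background bursts are never placed in any post-cue
5-s window. Without this rule the recovered post-cue rate would
estimate `p_post + (1 − p_post)·p_pre` rather than `p_post`, and the
generator's parameters could not be validated separately — the
parameter-recovery property would be unsatisfiable by construction.
(The block immediately *before* each cue is ordinary background: that
is precisely what the pre-cue rate measures.)

**Cohorts.** `generate_cohort()` draws per-participant probabilities
from normal distributions matched to the target cohort's moments
(post 0.66 ± 0.2245, pre 0.3481 ± 0.1412), *clamped* to [0, 1] rather
than resampled: the point mass at 1 mimics ceiling participants who
respond to every cue, which the real cohort contains. Survey sheets are
drawn item-wise around a person-level latent trait with targets near
the reported cohort means (SUS ≈ 80, QUEST ≈ 4.5, IMI subscales 4.9–6.2
with pressure/tension ≈ 2.8); between-participant score variance is
smaller than in real cohorts, so survey draws support plumbing and
power checks, not psychometric claims.

**What a green test does not establish.** The generator's bursts are
clean, stationary and collision-free by design; real data contain
tremor, transport artifacts, posture shifts and non-wear that is not
crisp. Recovery of `p_post`/`p_pre` on synthetic cohorts validates the
estimator chain, not the threshold's clinical validity. The published
compliance (94.0 ± 8.7%) and data-capture figures depend on unreleased
raw device data and are deliberately not simulation targets; compliance
is instead pinned by exact gap arithmetic on constructed inputs.

## Scoring and cohort statistics

* **SUS** uses the standard rule (odd items contribute score − 1, even
  items 5 − score, total × 2.5). Abbreviated descriptions that omit the
  −1 on positive items cannot yield the documented 0–100 range, so the
  standard rule is the only consistent reading.
* **QUEST** is the mean of 12 items; missing items are an error by
  default (imputation by the mean of answered items is opt-in and
  logged). The published t statistics for QUEST are consistent with a
  threshold of 4, not the stated midpoint 3; the report therefore
  carries the test against both thresholds rather than silently
  adopting either.
* **IMI**: reverse items are scored 8 − response before subscale
  averaging. The item→subscale map (subscale sizes 7/5/7/7/6/5, summing
  to 37) and the reverse set are configuration with documented
  defaults; the defaults are a repo convention and must be checked
  against the concrete instrument before cross-study comparisons.
* **Tests**: one-sided one-sample t against thresholds with two-sided
  90% CIs, and the paired t on post − pre differences with a 95% CI —
  the reporting conventions of the target literature. No multiplicity
  correction is applied to the planned tests. Summary-statistic entry
  points exist so published t values can be reproduced from printed
  means/SDs; with 1-decimal inputs, reproduction is only good to ≈ ±0.3
  for large t.

Tests are suppressed, never fabricated, when fewer than two
participants contribute or differences are constant.

## Numerical and design choices in brief

* Session start times default to 3600/12600/21600 s into the window
  (wearers choose them in the field; any non-overlapping in-window
  choice is valid configuration).
* Cues are placed at `session_start + 30·(0, 1, …)`; the expected count
  is `sessions × floor(duration/interval)`.
* Logs are header + CSV (`timestamp_s, x_g, y_g, z_g`) with seconds
  since day start (ms precision) and accelerations at µg precision;
  unsorted rows are an error by default with an opt-in sort. Config is
  JSON with all defaults materialized on load.
* All generator randomness is seed-scoped (the caller's RNG stream is
  saved and restored), which is what makes byte-identical fixture
  directories and reports under a fixed seed testable.
* Scaled-down simulations: unit tests use 10-min or 1-h windows where
  the property under test does not depend on the full protocol; the
  parameter-recovery acceptance test uses the full 8-h, 180-cue
  protocol at 30 days per grid point (~5 min of the suite's runtime),
  and the report-level power check uses 5 replicates of a
  29-participant, 60-cue-day cohort — per-participant rate noise is
  negligible against between-participant spread there, so the shorter
  day does not change power materially.

## Known limitations

* The burst spectrum and background block process are conventions, not
  kinematics; no exercise-type (tap/assist/independent) differences are
  modeled beyond amplitude settings.
* The activity threshold is calibrated to the generator's noise model;
  real deployments must calibrate against their own resting data.
* Gyroscope/magnetometer channels and movement-quality recognition are
  out of scope.
* With 1-decimal published summaries, some printed t statistics are
  reproducible only within rounding-implied bands; the acceptance tests
  encode exactly which.
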