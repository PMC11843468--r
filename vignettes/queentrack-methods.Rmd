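---
title: "Inferring foundress-queen foraging from bidirectional RFID reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring foundress-queen foraging from bidirectional RFID reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queentrack)
```

## The measurement problem

A bidirectional RFID reader at a nest entrance produces a stream of
timestamped detections on two antenna boards (inner, nearer the nest, and
outer). A complete passage is two reads on opposite boards a few seconds
apart; everything else — re-reads of a loitering bee, single-board
detections when the tag missed one antenna, reads swallowed by a battery
change — is noise that must be resolved before any behavioural quantity
(trip duration, trips per day, in-nest stay structure) can be computed.
`queentrack` implements that resolution as a fixed, deterministic stage
order: collapse re-reads, pair, label, relabel lone reads, drop spurious
inner reads, build alternating trips and stays, filter micro-trips and
outage-spanning intervals. Determinism matters: identical input must give
identical output, and every raw read is accounted for exactly once
(paired, relabeled, collapsed, spurious, or unresolvable).

## Parameters and their defaults

All thresholds live in one validated object:

```{r}
pipeline_config()
```

* `pairing_window_s = 10` (strict `<`): the maximum plausible tunnel
  transit. Strictness is deliberate; a 10.0 s gap does *not* pair.
* `min_trip_s = 30` (strict `<`): out-of-nest records shorter than this
  are defecation trips or entrance-loitering, not foraging; a trip of
  exactly 30 s is retained.
* `foraging_max_h = 4`: the boundary between ordinary foraging trips and
  extended absences. Summaries of "foraging" exclude extended trips so a
  handful of multi-hour absences cannot skew means. `overnight_min_h = 8`
  flags overnight absences.
* `stay_short_max_s = 180` and `stay_mid_max_h = 4`: the trimodal stay
  classification (brief unloading visits / between-trip nest work /
  multi-hour or overnight residence). The MID class is closed on both
  ends: exactly 3 min and exactly 4 h are MID.
* `stage_window_days = 5`: the length of the early and late
  foundress-stage windows.
* `local_tz = "America/Denver"`: all arithmetic is UTC, but "a day of
  foraging" is a local-clock concept, so daily counts and stage windows
  use local calendar days.

## Numerical and procedural choices

Several points are underdetermined by the verbal filtering rules; the
package fixes them explicitly:

* **Tie-break.** Reads with equal timestamps sort INNER before OUTER —
  arbitrary but fixed, so a simultaneous opposite-board pair is labeled
  as an exit. With a 1 s reader clock this can only arise for
  sub-second transits.
* **Event time = second read of the pair** (passage completion). Trip
  durations therefore run from completion to completion and can differ
  from "first-read" durations by at most one transit time.
* **Re-read collapse before pairing.** Same-board runs with gaps under
  the pairing window collapse onto their first read, chained on raw
  adjacency. Without this, a re-read would strand genuine partner reads
  as lone reads.
* **Relabeling is a single pass** over the merged timeline of events and
  lone reads, using nearest-in-time neighbours with no gap limit. A lone
  read adjacent to another lone read is never relabeled, and a freshly
  relabeled read does not enable relabeling its neighbour.
* **Residual outer-board lone reads** (and inner reads not matching the
  standing-in-the-entrance signature) are excluded from the timeline and
  logged as unresolvable. The filtering rules define no direction for
  them, and inventing one would fabricate trips.
* **Stays spanning outages** are flagged invalid and excluded from stay
  statistics, mirroring the trip rule (stated only for trips); a stay
  whose interior contains a power gap could equally hide an excursion.
* **Trips/day denominator**: all calendar days from a queen's first to
  last foraging day inclusive, counting zero-trip days as zeros, because
  recording is continuous. The active-days-only alternative is available
  (`active_days_only = TRUE`).
* **Percentages** in the fate flow are emitted at one decimal and in two
  integer renderings (round-half-up and truncated), since summary
  figures in the literature use either convention.
* **Stage models.** The duration model uses the natural log. The stage
  factor has EARLY as reference, so the coefficient is the LATE−EARLY
  contrast; its p-value is a Wald normal test. The count model is a
  negative-binomial GLMM in mean/dispersion form (variance μ + μ²/θ),
  fitted by maximum likelihood with a Laplace approximation
  (`glmmTMB`); the duration LMM is REML (`lme4`). Queens with a
  foraging span shorter than two stage windows are excluded with a flag
  rather than given overlapping windows. Degenerate inputs (one queen,
  one stage, zero variance, all-zero counts, an inestimable Hessian)
  are refused with errors, not silently fitted.
* **Concordance matching** is greedy by minimal |Δt| with deterministic
  tie-breaks (earlier observer event, then earlier RFID event); an
  optimal non-crossing matching is available behind
  `method = "optimal"`. The default tolerance is 120 s — a wristwatch
  observation log and a reader clock cannot be expected to agree closer
  — and `concordance_sensitivity()` reports the 30/60/120/300 s ladder.
  A match with disagreeing directions counts as a sensor error, as does
  a match to a direction-unknown detection (an unresolvable lone read).

## What the generator emulates

`sim_config()` describes a "paper-like" queen: an alternating renewal
process of in-nest stays and out-of-nest trips.

* **Trips** are lognormal, fully parameterized from the printed targets
  of the study system — median 16.1 min and mean 21.9 min, giving
  `meanlog = log(966)` and `sdlog = sqrt(2 log(21.9/16.1)) ≈ 0.784`.
  With probability 0.014 per trip (21 of 1471 recorded trips) the queen
  stays out overnight, drawn lognormal around a 13.1 h mean.
* **Stays** are a three-component lognormal mixture targeting class
  means of 52.6 s, 27 min and 13.2 h. Weights 0.32/0.62/0.06 and
  log-sds 0.6/0.8/0.2 were calibrated once, at design time, so that the
  *realized* class means of pipeline-recovered stays sit within a few
  percent of the targets and daily trip counts land near 12/day.
* **The day window** (06:00–20:00 local) constrains trip initiation.
  Night handling is the one genuinely structural choice: naive rejection
  sampling of the mixture biases realized durations, because the
  rejection chain near the evening boundary preferentially accepts short
  stays and inflates accepted long ones. Instead, the first short/mid
  draw that would cross the evening window end sends the queen into an
  overnight stay drawn from the long component and landing in a later
  day window. Long draws and pre-dawn entrances are rejection-sampled
  into the window.
* **Stays are floored at 15 s.** A turnaround faster than the pairing
  window plus transit is unresolvable by the sensor in principle — the
  collapse rule would alias it into a single passage — so the generator
  does not produce it. Real queens do make 1 s appearances in a doorway;
  this floor is a stated sensor-resolution assumption, not a biological
  claim.
* **The sensor model**: each passage yields a read on the first board
  and, after a uniform 1–3 s transit, on the second; each read is
  independently lost with one minus its board's detection probability
  (default 0.95 per board); detections are re-read with probability 0.1;
  timestamps are floored to whole seconds (the reader clock's
  resolution); reads inside scheduled battery outages (default every
  84 h for 300 s) are deleted. The transit minimum is 1 s rather than
  sub-second because a 1 s clock cannot represent faster transits
  without colliding both reads onto one timestamp, where the fixed
  tie-break could invert a direction. Board failures are independent;
  there is no correlated failure mode (a tag tilted away from both
  antennas), which is the main way the model is optimistic.
* **Worker emergence**: if set, the queen ceases foraging a uniform 0–7
  days later, abruptly.

What the generator does *not* emulate: weather- or resource-driven
day-to-day rate variation, duration drift across the season (stage
effects are injected directly by `simulate_stage_trips()` /
`simulate_stage_counts()` when models are calibrated), invader-queen
behaviour (a second tag is handled mechanically, not behaviourally),
clock drift between reader and observer, and correlated detection
failures. Passing recovery tests on this generator therefore shows the
*filtering rules* are implemented faithfully and are statistically
well-behaved under realistic event densities — not that every feature of
field data is captured.

## Problem sizes in the test suite

The suite checks exact recovery under perfect sensing over 50 simulated
two-week recordings; equivalence with a brute-force pairing reference
(exhaustive enumeration of adjacent-pair matchings, earliest-first
maximal selection) on 1,000 random streams of up to 12 reads; a 20-read
hand-traced fixture exercising every removal path; stay-class mean
recovery pooled over five 30-day runs at perfect detection (a single run
holds only a few dozen long stays, so pooling keeps Monte-Carlo noise
well below the 10% recovery margin being tested); and stage-model
calibration at six queens with 40 trips per stage (type-I coverage over
200 seeds, power and sign recovery over 100 and 40 seeds). These sizes
are the package's own choices, balancing statistical resolution against
a test suite that stays pleasant to run.

## Known limitations

* The pipeline reports missed passages (same-direction event runs) but
  never imputes them; two true trips separated by a fully missed
  entrance appear as one anomaly and no trip.
* Unresolvable lone reads are dropped from the event timeline; at low
  detection probability this under-counts trips, which is visible in
  the degradation property (mean inferred trip count is non-increasing
  in detection probability) rather than corrected.
* With a single queen, per-queen random intercepts are inestimable and
  the stage models refuse to fit; this is inherent to the design, not a
  software limit.
* Calendar-day quantities assume one contiguous timezone for a study;
  multi-site data spanning timezones need per-site configurations.
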