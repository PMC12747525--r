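---
title: "Methods: rule-based scoring of fly aggression and courtship from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based scoring of fly aggression and courtship from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flybouts)
```

## What this package computes

Pairs of *Drosophila melanogaster* in small circular arenas display a
repertoire of stereotyped social behaviors: males fight with lunges, and
court with unilateral wing extension (song), following, circling, and
mounting that either ends quickly (attempted copulation) or persists
(copulation). Modern workflows film the pair (typically 30 fps), run a
tracker (e.g. Caltech FlyTracker) to obtain per-frame centroids, body
orientations and wing angles, and then score behaviors from those
trajectories.

`flybouts` implements this trajectory-to-ethogram step as deterministic
rules, together with the evaluation framework used to benchmark automatic
scorers against frame-by-frame manual annotation, and a synthetic session
generator that makes the whole pipeline testable without any video. The
rules are the classical kinematic definitions that circulate in the
Drosophila aggression/courtship literature (lunge strike speed near
200 mm/s; wing angle exceeding 30 degrees; a male 2-5 mm behind a walking
female; sideways orbiting; mounting bands split at 45 s), not a trained
classifier: a learned scorer can adapt to variation that fixed thresholds
miss, and no equivalence with any trained model is claimed. What the rule
stack offers is transparency, portability and exact testability.

## Data model

* **Frames** are 0-based and contiguous; **intervals are half-open**
  `[start, end)`, so a bout's frame count is `end - start` with no
  off-by-one corrections anywhere.
* Exactly two flies with fixed roles: the focal `male` and its partner
  `other` (a female in courtship, a male opponent in aggression). Identity
  switches are assumed to have been repaired upstream in the tracker.
* Coordinates are millimetres with the origin at the arena center; body
  orientation `theta` is in radians (direction of the head), wing angles
  in degrees in `[0, 180)`. CSV is the only interchange dialect; binary
  tracker exports must be converted by the user, who is also responsible
  for the degree/radian convention of their tracker.
* `T = 0` sessions are rejected everywhere; single-frame sessions are
  valid containers but have no defined velocities.

## Features

All detectors consume a per-frame feature table (`compute_features()`):
speeds, inter-fly distance, the male's facing angle, the partner's rear
angle (180 degrees = male directly behind), the unwrapped angular position
of the male around the partner and its derivative, the sideways fraction
of the male's motion relative to its own body axis, and the larger wing
angle.

Velocities are central differences scaled by fps (one-sided at the two
endpoints): unbiased for smooth motion and exact for straight
constant-velocity travel. Angular position is unwrapped by accumulating
wrapped frame-to-frame increments, so no spurious ±π jumps enter the
angular velocity. The sideways fraction uses an `eps = 1e-9` guard so a
stationary fly scores 0 rather than NaN. An optional centered moving
average (default off) can damp tracker jitter; the simulator produces
jitter-free tracks, so none of the shipped tests exercise it.

**Peak speed.** A lunge is an impulsive, essentially single-frame event.
A central difference spans two frame intervals, so at 30 fps it averages
the strike displacement with the stationary neighbor frames, and inside a
13 mm arena it can never exceed 13 × 30 / 2 = 195 mm/s — below the
200 mm/s lunge criterion. The feature table therefore also carries
`peak_speed_mm_s`, the larger of the two adjacent-frame displacement
speeds at each frame, which is the natural speed estimator for impulses;
the lunge detector uses it, everything else uses the central-difference
speed.

## Detector rules and their tunables

All thresholds live in `classifier_params()` and can be written to or
read from a flat YAML file.

| Behavior | Rule (candidate frame predicate) | Persistence |
|---|---|---|
| lunge | peak speed ≥ 200 mm/s, distance ≤ 5 mm, facing ≤ 45° | single frame; qualifying frames within 3 frames collapse to the peak-speed frame (earliest on ties) |
| wing extension | max wing angle **strictly** > 30° | ≥ 0.5 s (15 frames at 30 fps) |
| following | 2 mm ≤ distance ≤ 5 mm, rear angle ≥ 120°, both speeds ≥ 2 mm/s | ≥ 25 frames |
| circling | distance ≤ 5 mm, \|angular velocity\| ≥ 1 rad/s, sideways fraction ≥ 0.5 | ≥ 0.5 s |
| mounting | distance ≤ 0.5 × mean pair body length, both speeds ≤ 2 mm/s | ≥ 10 frames; runs ≥ 1350 frames (45 s) are copulation, shorter runs attempted copulation |

Decisions worth recording:

* **Persistence units.** The classical wing-extension/circling persistence
  is quoted as 13 frames at 25 fps, i.e. about 0.5 s. Storing it in
  seconds and converting with `round(s × fps)` keeps the intent portable
  across frame rates (15 frames at 30 fps); following is quoted directly
  in frames (25) and is kept that way. Both interpretations remain
  reachable through the config. Mounting bands are stored in frames and
  assume 30 fps.
* **45 s boundary.** A mounting run of exactly 1350 frames at 30 fps is
  copulation (the "at least 45 s" reading wins over frame-count phrasings
  that are self-contradictory at exactly 1350).
* **Rear sector.** "Behind the female" is operationalized as a rear angle
  of at least 120 degrees — the rear half-plane with margin; published
  rule sets state only the distance band.
* **Unobservables.** The 45-degree body-pitch component of a lunge and
  "abdominal curling without mounting" have no signature in planar
  centroid tracks and are deliberately not part of any rule.
* **Copulation dominance.** In `classify_all()`, frames labeled
  copulation are cleared of concurrent wing-extension/following/circling
  labels, so a merged pair is not double-counted as active courtship.
* **Lunges stay atomic.** `normalize_bouts()` merges overlapping or
  frame-adjacent bouts of duration behaviors, but lunges are counted
  events: adjacent single-frame lunges are never merged (the detector's
  refractory collapse already guarantees a ≥ 3-frame separation).
* **Duration floor.** The post-filter "exclude bouts shorter than 98% of
  manual bouts" is read as *retain a floor that 98% of manual bouts meet*:
  the floor is the `(1 - coverage)` quantile of the reference durations
  with lower interpolation (`stats::quantile(type = 1)`), and the coverage
  is configurable because the sentence admits other readings.

Lunge counts aggregate into the conventional intensity categories
(0-70 low, 71-160 moderate, 161-300 high, > 300 hyper-aggressive).

## Evaluation conventions

Bout-level matching uses the field's asymmetric many-to-one rules: a
truth bout overlapped by at least one frame of any prediction is one TP
(several fragments still count once); a single prediction spanning
several truth bouts scores one TP per truth bout; unmatched predictions
are FP, unmatched truth bouts FN. Consequently `tp + fn == n_truth`
always, TP counts truth bouts while FP counts predicted bouts, and
bout-level precision mixes the two unit systems — this is kept literally,
with an optional `symmetric = TRUE` mode that counts TP on the prediction
side. Touching half-open intervals share no frame and do not match.
Frame-level matching is the ordinary per-frame confusion matrix and is
symmetric (swapping prediction and truth exchanges precision and recall).

Precision, recall and F1 are defined as 0 whenever their denominator is
0, so empty sessions and empty predictions produce clean reports rather
than NaN. The behavioral index is the fraction of *all* recorded frames
spent in the behavior (no post-acclimation trimming). Method comparison
across videos uses ordinary least squares with an intercept, with
R² = 1 − SSres/SStot computed from the residuals.

## The synthetic session generator

`simulate_session()` is the package's test harness and defines its study
conditions: 30 fps recordings in the standard arenas (aggression 13 mm ×
20 min, courtship 11 mm × 15 min) plus a desk preset (11 mm × 60 s,
1800 frames) sized so that the complete suite — including 20-seed recovery
runs per behavior — executes in seconds.

Outside scheduled bouts the two flies perform slow, home-anchored random
walks near opposite walls. The baseline is built to violate *every*
detector predicate by construction: per-frame displacement is capped at
1.8 mm/s ÷ fps (below the 2 mm/s walking threshold), the home anchors
keep the pair more than 6 mm apart, and baseline wing noise stays below
20 degrees. Scheduled bouts are injected by overriding kinematics with
rule-satisfying templates rather than by physics: wing angles drawn from
[45°, 70°]; a lunge staged as a strike from ~9.5 mm to ~1.7 mm at an
adjacent-frame speed drawn from [230, 245] mm/s (the widest impulse that
fits inside an 11 mm arena with staging margin); following as two flies
walking the same circle at 5 mm/s with a [2.8, 4.2] mm gap; circling as a
3 mm-radius orbit at 2 rad/s with the body axis pinned on the partner;
mounting as a held 0.4 mm contact. Two-frame straight-line transitions
join templates to the baseline; during a transition the partner is
oriented at the male (rear angle ≈ 0 kills following) and the male along
its own motion (sideways ≈ 0 kills circling), and transition steps stay
under 200 mm/s, so transitions never satisfy a predicate themselves.
Central differences blur at most one frame at each template edge, which
is why recovered bout boundaries are guaranteed only to ±2 frames and
scheduled durations must clear each persistence threshold by 20%.

A single integer seed drives one session-level generator; identical seeds
give bit-for-bit identical sessions. What the simulator does **not**
emulate: tracker noise and identity swaps, occlusion artifacts, female
receptivity dynamics, gradual accelerations into and out of behaviors, or
ambiguous borderline kinematics. Perfect recovery on simulated sessions
therefore demonstrates the internal consistency of detectors, converters
and metrics — not classifier performance on real videos, which published
benchmarks place in the 75-95% F1 range depending on behavior.

`corrupt_bouts()` complements the generator: it derives a degraded
"prediction" from a truth table (deletions, one-frame-gap splits,
overlap-preserving boundary jitter, insertions into free regions) while
returning the exact bout-level TP/FP/FN its edits imply. Jitter is
clamped so every piece keeps at least one frame inside its source bout
and never touches a neighboring truth bout, which is what makes the
bookkeeping exact rather than approximate; `match_bouts()` must reproduce
it on every seed, and the shipped tests check 100 seeded runs.

## Numerical choices

* Frame/second conversion is `round(seconds × fps)` with R's
  ties-to-even; quantities that matter are integers well clear of ties.
* The lunge refractory tie-break is the earliest maximal-speed frame.
* `stats::quantile(type = 1)` (lower interpolation) for the duration
  floor, which is also immune to floating-point noise near exact
  quantile indices.
* Interval overlap is delegated to `IRanges` (half-open intervals are
  converted to closed integer ranges); the test suite re-derives every
  count with an independent all-pairs scan.
* Degenerate inputs: empty bout tables and all-false ethograms are valid
  and flow through every operation; metrics with zero denominators are 0;
  sessions must have at least 2 frames before features are defined.

## Problem sizes in the shipped tests

The suite fabricates feature tables directly for boundary cases (e.g. a
1350-frame mounting run), uses 200-1000-frame random tables for oracle
comparisons (1000 random matching instances, 100 corrupter seeds), runs
20 seeded desk sessions per behavior for end-to-end recovery, and one
full-length 36,000-frame aggression session for the I/O and preset
checks. These sizes were chosen so the defaults demonstrate every
contract at full strictness while the whole suite stays fast enough to
run on every change.

## Known limitations

* Rules are not a substitute for a trained classifier on real, noisy
  video-derived tracks; thresholds will need tuning per rig, and the
  duration-floor filter expects a manual reference set.
* Only dyadic sessions with fixed roles are supported; groups and
  identity repair are out of scope.
* Wing-extension laterality (left vs right) is collapsed into the larger
  wing angle.
* The mounting proxy (sustained centroid merge at low speed) cannot
  separate mounting from prolonged stationary contact, which real
  assays disambiguate visually.
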