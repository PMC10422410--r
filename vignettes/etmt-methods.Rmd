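---
title: "Scoring eye-tracked Trail-Making Tests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring eye-tracked Trail-Making Tests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etmt)
```

This vignette documents the models implemented in `etmt`, the parameters
that matter, the design decisions taken where the procedure was genuinely
open, and what the synthetic validation does and does not establish.

## The task and the data

The Trail-Making Test presents scattered targets to be visited in
ascending order: numbers 1–8 or 1–25 for the two TMT-A stimuli, and the
alternating number–letter chains 1-A-2-B-3-C-4-D and 1-A-…-12-L for the
two TMT-B stimuli. Each target is an area of interest (AOI), modeled here
as a disc of radius 40 px placed by seeded rejection sampling with a
minimum center separation of 2.5 radii (bounded at 10,000 retries, so a
canvas that is too small fails deterministically rather than looping).
TMT-B's "ascending combination" is fixed to the standard 1-A-2-B-…
alternation.

A session is four trials, one per stimulus, recorded at 60 Hz as rows of
(timestamp, stimulus, gaze x/y in screen pixels, pupil diameter, validity
flag). Coordinates use the screen convention: origin top-left, y
increasing downward; timestamps are milliseconds from trial start.

## Fixation detection

Vendor analysis suites detect fixations with proprietary settings, so the
package provides its own deterministic detector: dispersion-threshold
identification (I-DT). A window grows until it spans the minimum duration;
if its bounding-box dispersion (width + height) is within the threshold it
extends greedily, emits a fixation (onset, span, centroid), and restarts
after it. Defaults: dispersion 50 px, minimum duration 100 ms — common
desk-scale values; both are configurable everywhere they are used.
Invalid samples split runs rather than being interpolated: interpolation
would manufacture gaze where the tracker lost the eye, and splitting is
conservative and easy to reason about in tests. Exactly reproducing any
particular vendor's segmentation is not attempted.

## The thirteen features

Low-level features are fixation statistics (count, total time, percentage
of trial, mean duration). Middle-level features are per-AOI: dwell time,
dwell percentage, glances, revisits (distinct visit runs minus one, where
a visit run is a maximal streak of consecutive fixations in one AOI), and
first-fixation duration.

High-level features derive from the *scanpath string*: each fixation maps
to the AOI containing its centroid (boundary counts as inside;
out-of-AOI fixations contribute nothing), and consecutive duplicate
labels are collapsed. Collapsing is a deliberate choice: a dwell of
several fixations on one target is one *visit* — dwell length is already
captured by the middle-level features — and the reference worked example
(scanpath `6 1 2 3 4 5 6 7 8` on the 1–8 trail) shows no immediate
duplicates although multi-fixation dwells certainly occurred. The
uncollapsed string remains available behind `collapse = FALSE`.

- **FH1, scanpath score** — token-level Levenshtein distance between the
  observed string and the expected trail. Tokens are atomic, so the
  two-character label "12" costs one edit like any other; the worked
  example above scores exactly 1 (one spurious leading visit).
- **FH2, total time** — the trial span, summed over the four trials for a
  session. Both per-trial and session totals are exposed, since either
  granularity can be of interest.
- **FH3, error rate** — out-of-AOI fixations *plus* wrong visits. Wrong
  visits are counted with a pointer walk along the expected sequence: a
  token matching the next expected label advances the pointer, anything
  else counts one error. The two error kinds are summed because both
  happen in practice and the worked example (an early glance at target 6,
  "a single error") requires wrong-visit counting, not just out-of-AOI
  counting.
- **FH4, inattentional blindness** — repeated-pattern events in the
  scanpath. Scanning left to right, the longest run of ≥ 2 tokens
  starting at the cursor that already occurred earlier (ending before the
  cursor) counts one event and is skipped; otherwise the cursor advances
  one token. The minimum pattern length of 2 is forced by consistency:
  a single-token revisit (the repeated "6" in the example above) is *not*
  blindness, while re-viewing the run over targets 6 and 7 is. The
  parameter is configurable.

**Session aggregation.** The per-participant feature vector has 13
entries: FL1, FL2, FM1, FM3, FM4 and FH1–FH4 are summed across trials
(FM features first aggregated across AOIs within a trial: sums for
FM1/FM3/FM4, means over all AOIs for FM2/FM5), and FL3, FL4, FM2, FM5 are
averaged. Counts and times add naturally; percentages and averages do
not. The aggregation rule is recorded in each vector's provenance
attribute, and a participant missing a trial is aggregated over the
available trials with a warning rather than rejected.

## The two Mamdani scores

Each scoring system has two inputs with three trapezoidal sets each, one
output on [0, 1], a complete 9-rule base, min AND, min implication, max
aggregation, and centroid defuzzification on a uniform grid (step 1e-3; a
10×-finer grid shifts the centroid by well under 1e-3).

**Normalization.** The raw features live on layout-dependent scales, so
inputs are normalized and capped at 1: FH1 and FH3 by the expected-trail
length (65 for a full session), FH2 by a reference maximum completion
time (180 s), FH4 by a saturation cap of 3 events. The reference time and
cap are configurable; the defaults are chosen so that an unimpaired
session sits deep in the "low" input region and a strongly impaired
simulated session reaches the "high" region.

**Membership functions.** The defaults are a *plateau-covering* partition:
low = (0, 0, 0.3, 0.5), medium = (0.1, 0.3, 0.7, 0.9),
high = (0.5, 0.7, 1, 1) — adjacent plateaus touch, so every point of the
universe has membership 1 in at least one set. This choice is what makes
the defuzzified output monotone in each input: with a partition whose
plateaus do not touch (e.g. the common 0/0.2/0.4-style spacing), the max
of two adjacent memberships dips below 1 at the crossover, the clipped
consequent mass shrinks and then recovers, and the centroid moves
*non-monotonically* — a score that momentarily improves as performance
worsens. The monotonicity of both systems in both inputs is asserted on a
grid in the test suite.

**Rule base.** Both inputs of each system are "badness" quantities, so
the matrix maps low inputs to a high score: (L,L) → H, (L,M) → H,
(M,L) → H, (M,M) → M, (L,H) → M, (H,L) → M, (M,H) → L, (H,M) → L,
(H,H) → L. It is symmetric, which yields an engine-level consistency
check (swapping the inputs leaves the output unchanged). All nine
consequents and all breakpoints can be overridden through the JSON config
(`write_fis_config()` / `read_fis_config()` round-trip bit-exactly).

If no rule fires at all — possible only with a misconfigured universe —
the engine returns the universe midpoint flagged as degenerate rather
than failing.

**Bands and deficit flags.** Scores are banded low / medium / high at
thirds of [0, 1] (low is [0, 1/3), medium [1/3, 2/3], high above). A high
visual-search-speed score grades the processing-speed and
visual-attention deficit indications "low", and analogously for the five
focused-attention-linked indications (motor impairment, attentional
disengagement, memory, neuropsychological impairment, executive
functioning).

## The ANFIS cognitive-impairment score

Cohort feature vectors are z-standardized (zero-variance features get
unit scale) and clustered with k-means, k = 3: Lloyd's algorithm with
k-means++ seeding, 10 restarts, best inertia kept, all from one seed.
The clusters are ordered by ascending mean standardized FH2 + FH3 —
slower completion with more errors means higher impairment — and labeled
0, 0.5, 1. This ordering stands in for the expert labeling step of a
clinical workflow; the encoding is a convention.

The ANFIS is a Takagi–Sugeno system with one rule per cluster (scatter
partition): Gaussian premise per input per rule, linear consequent per
rule. A grid partition with three sets per input is not viable at 13
inputs (3^13 ≈ 1.6 M rules); "three membership functions" is read as
three rule-wise Gaussian sets per input dimension. Rules initialize at
the cluster means and standard deviations (widths floored at 0.1 so a
degenerate cluster cannot produce a zero-width premise), consequents at
zero weights with the cluster label as intercept.

Training is hybrid, 30 epochs by default on a label-stratified 75/25
split: each epoch first solves *all* consequent coefficients globally by
ridge-regularized least squares (ridge 1e-8, for numerical stability of
the Gram matrix) on the design matrix weighted by normalized firing
strengths — which can never increase training error given fixed premises
— then takes one full-batch gradient step (rate 0.01) on the premise
centers and widths against mean squared error, with widths clamped
positive. If every premise underflows for some input, the forward pass
falls back to the nearest-center rule instead of dividing by zero.
Reported error statistics are RMSE, error mean, and error standard
deviation; the standard deviation uses the sample (n−1) convention,
stated here because either convention is defensible.

The final score is the forward pass clipped to [0, 1] and banded at
thirds. Models serialize to JSON with 17 significant digits, so a
write/read round trip reproduces predictions bit-exactly.

## The synthetic cohort generator

The simulator exists so that every stage — reader, detector, features,
both fuzzy systems, clustering, training — can be validated end to end
without clinical recordings. A simulated participant walks the expected
trail; at each transition a *stray* fixation is inserted with probability
`stray_prob` (60% onto a wrong target — never the previous or next
expected one, so each stray yields exactly one countable error — and 40%
onto a point far outside every AOI), and with probability `revisit_prob`
the previous two visited targets are replayed, which is precisely the
repeated-run signature FH4 detects. Dwells are normal (250 ± 50 ms)
truncated above 120 ms — the truncation sits above the detector's 100 ms
minimum so that every emitted dwell survives detection and a
zero-impairment run is exactly clean — and all times dilate by
`slow_factor`. Samples are emitted at 60 Hz with Gaussian jitter
(5 px sd); transit samples between targets are emitted as *invalid*,
modeling tracking loss during saccades and exercising the detector's
run-splitting path.

The default group profiles are low = (stray 0.02, revisit 0.01, slow
1.0), medium = (0.15, 0.15, 1.5), high = (0.35, 0.35, 2.5): an
essentially clean performer, a moderately erratic one, and a strongly
impaired one whose completion time is 2.5× dilated. These were chosen
once as plausible behavioral contrasts between unimpaired and impaired
performers and produce overlapping but separable groups.

What the simulator does *not* model: saccade main-sequence dynamics,
blinks, pupil responses, calibration drift, or any disease-specific
signature. Passing the synthetic validation therefore shows that the
pipeline recovers *the structure the generator encodes* — monotone
feature response, group recovery, score ordering — not that it screens
real patients; clinical validity requires clinical data.

## Validation and problem sizes

The test suite checks, among others: Levenshtein against a recursive
oracle (1,000 random token pairs, plus symmetry and triangle
inequality); the blindness count against an exhaustive-search oracle on
*every* sequence of length ≤ 8 over a 4-token alphabet (87,380
sequences); centroid defuzzification against a 10×-finer grid (100
random activations, agreement within 1e-3); monotonicity of both scoring
systems on a 50-point grid; the ANFIS forward pass against the
closed-form Σ w̄ f expression at 1e-12 (100 random 3-rule models);
function recovery on a stated 2-input, 2-rule generator (n = 200, noise
sd 0.01, test RMSE < 0.05 after 30 epochs); and a 30-participant
simulated cohort where k-means recovers the generating groups with
adjusted Rand index ≥ 0.8 and the mean cognitive-impairment score is
strictly increasing across the true groups. Cohort sizes in the suite
(12–30 participants) keep the whole run near a minute while leaving the
group structure statistically unambiguous.

## Known limitations

- The fuzzy membership breakpoints, rule consequents, and normalization
  scales are package conventions, selected for monotone, band-faithful
  behavior; they are not calibrated against clinical outcomes.
- Saccade- and pupil-based features are out of scope; the feature set is
  fixation-based.
- The expert-labeling step is approximated by a severity ordering of
  k-means clusters; with real cohorts a clinician should review the
  labels before training.
- Scores of participants missing trials are computed over the available
  trials and flagged, which biases summed features downward; comparisons
  should use complete sessions.
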