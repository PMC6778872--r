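---
title: "Detecting individually salient moments from wearable autonomic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting individually salient moments from wearable autonomic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(physioevents)
```

## The problem

Wearable fingertip sensors record three autonomic-nervous-system channels
— electrodermal activity (EDA, µS), skin temperature (°C) and heart rate
(bpm) — at a nominal 15 Hz. Transient changes in these channels accompany
moments that a wearer experiences as salient: an orienting electrodermal
reaction (EDR), a heart-rate acceleration or deceleration outside the
usual respiratory pattern, or a vasoconstriction/vasodilation switch
visible as a fingertip temperature trend change. `physioevents` turns a
raw session recording into a short list of candidate salient moments,
each with a ±10 s clip window suitable for reviewing the synchronized
video of the session, and tailors the detection thresholds to an
individual from annotated sessions and reviewer feedback. The intended
application is dementia care, where the wearer may be unable to
self-report significant moments and a caregiver reviews the clips
instead; nothing in the package is specific to that population.

## The processing model

### Preprocessing

Each channel passes through three causal stages and emerges at 2 Hz:

1. **Artifact repair.** Samples are flagged when they are exactly zero
   (sensor dropout) or deviate by more than three standard deviations
   from the mean of the preceding second. The two rules are combined by
   OR — each independently indicates hardware error, and requiring both
   simultaneously would almost never trigger. When the preceding window
   has zero variance the deviation rule is skipped: a clean constant
   signal must not flag itself. Flagged samples are replaced by the
   median of unflagged neighbours inside a centred window (order 75
   samples for EDA, 1 for temperature and heart rate; heart rate's order
   is not independently specified anywhere, so it follows the
   temperature setting by parsimony). A run of flagged samples that
   exhausts its window falls back to the nearest unflagged value — a
   documented convention, since no reference behaviour exists for that
   case.
2. **Downsampling.** A non-overlapping moving average over 0.5-second
   windows aligned to the first sample. Windows are delimited *in time*:
   at 15 Hz a window holds 7.5 samples on average (alternating 7 and 8),
   which is the only reading under which the output is exactly 2 Hz. A
   trailing partial window is discarded.
3. **Modality smoothing.** EDA: a one-Euro filter (speed-adaptive
   exponential smoothing; `mincutoff = 50`, `beta = 4`, derivative
   cutoff fixed at the published default of 1 Hz). Temperature: an
   exponential decay filter `y[k] = p·y[k−1] + (1−p)·x[k]` with
   `p = 0.95`. Heart rate: a cubic smoothing spline in the `csaps`
   convention, minimizing `p·Σ(y−x)² + (1−p)·∫(y″)²` with `p = 0.001`,
   realized through `stats::smooth.spline` with
   `lambda = (1−p)/(p·range(t)³)` (the cubed range compensates for
   `smooth.spline`'s internal rescaling of time to [0, 1]).

Two numerical notes. A `mincutoff` of 50 is far above the 1 Hz Nyquist
limit of a 2 Hz series, so the one-Euro stage is nearly transparent at
this rate; it is kept for fidelity to the published parameterization and
becomes active if the filter is run at higher rates via `filter_config()`.
And at `p = 0.001` the spline suppresses everything but multi-minute
structure: it tracks slow heart-rate trends well but attenuates a 20 s
triangular excursion by roughly a third, which matters when interpreting
fitted prominence thresholds (below).

### Signal quality

A rule table scores each 0.5 s step of the EDA and temperature channels
in [0, 1]; rules that fire propose scores, and the step takes the
*minimum* over fired rules (worst evidence dominates — the table itself
does not state a combination rule). EDA: any consecutive-sample change
above 3 µS within the trailing 15 s window scores 0.4; a trailing 25 s
window whose consecutive differences all stay within 0.001 µS scores 0.1;
values at or below 0.02 µS score 0, above 20 µS 0.65, above 30 µS 0 (the
tiers are treated as cumulative, the more extreme row winning through the
min). Temperature: a flat trailing 25 s window (differences ≤ 0.0001 °C)
scores 0.5, as do values below 15 °C. Before a rule's window has fully
elapsed only the instantaneous range rules are evaluated. No heart-rate
quality rules exist in the source material and the session mask uses only
EDA and temperature, so none are invented here.

After a session completes, the mean µ and standard deviation σ of each
SQI series give a binary mask: a step is invalid when either channel
falls below its µ − σ. Invalid steps are excluded from event selection.
This is deliberately relative — a session-specific noise floor — rather
than an absolute quality bar.

### Features, score and selection

At each 2 Hz step three non-negative feature series are computed:

* `EDR(t)`: the rise of EDA over the trailing `t_EDR` = 10 s window
  (current value minus window minimum), kept when it reaches
  `A_EDR` = 0.05 µS — the canonical EDR definition — else 0.
* `Δtemp(t)`: the range (max − min) of temperature over the trailing
  `t_temp` = 10 s window, kept when it reaches `ΔT` = 0.01 °C. A
  stricter `"reversal"` mode additionally demands a slope sign change
  inside the window; the default `"range"` mode matches the worked
  numerical examples the method is validated against.
* `HR_var(t)`: the topographic prominence of local heart-rate maxima and
  minima (minima via the negated series), kept when it reaches
  `minPeakProminence` = 10 bpm; end samples are never peaks.

The feature *strength* is the physical magnitude itself (µS, °C, bpm).
This makes per-individual weighting factors interpretable as
unit-balancing multipliers. The salience score is the weighted sum
`S = a·EDR + b·Δtemp + c·HR_var` with all weights defaulting to 1.
Although the score definition nominally constrains weights to [0, 1],
individually tailored configurations in practice use scaling factors well
above 1 (up to ~9), so the implementation accepts any non-negative
weight. Threshold comparisons use `x ≥ thr − 10⁻⁹` so printed values such
as 0.05 µS or 0.01 °C fire exactly at threshold despite floating-point
representation.

Events are the top-`N` score steps (default `N` = 5, configurable to the
7 or 10 used in later sessions) chosen greedily, skipping invalid-quality
steps and any step within `min_sep_s` = 20 s of an already chosen event,
ties broken toward the earlier time. The 20 s separation makes the ±10 s
clip windows disjoint. Greedy, not globally optimal, selection is a
deliberate design: it mirrors "take the highest-scoring events", and the
test suite documents an instance where the two differ.

### Tailoring

Stage one (`fit_from_annotations()`) automates threshold replacement
from annotated recordings: the three feature magnitudes are measured in
±5 s epochs around each `significant` annotation, those observed values
seed the candidate threshold lists (together with the user grid and an
`Inf` "channel off" candidate), and a deterministic grid search over
thresholds, windows and weight sets retains the candidate maximizing
**precision at fixed N** — TP/(TP+FP) with an event counted as TP when a
significant annotation lies within ±10 s (the clip half-width), each
annotation matching at most one event, nearest pairs first. "Accuracy"
is not formally defined in the source procedure; precision-at-N is the
operationalization chosen here because the event cap is fixed per
session and recall enters separately through missed-moment feedback.
Ties are broken first toward more true positives, then toward the most
specific (largest) thresholds — the analogue of replacing defaults with
the observed epoch values — and finally toward the earliest candidate in
the deterministic expansion order, so a grid containing only the
defaults returns the defaults (`seed_candidates = FALSE` searches the
grid verbatim).

Stage two (`iterate_feedback()`) consumes TP/FP verdicts on presented
events plus reported missed moments, and performs a local search over
the grid neighbourhood of the current parameters (one grid step per
field, one field at a time, plus the weight sets), maximizing the margin
(TPs retained) − (FPs retained) + (missed recovered). Ties keep the
current parameters, so all-TP feedback with nothing missed is a fixed
point. How conflicting goals were resolved in the original manual loop
is unrecorded; this margin is the package's own explicit objective.

## The synthetic-session generator

`generate_session()` produces 15 Hz three-channel recordings with known
ground truth: per-channel baselines (4 µS, 33 °C, 72 bpm), white
Gaussian noise (0.005 µS, 0.002 °C, 0.5 bpm), a slow 300 s sinusoidal
drift (0.02 µS, 0.05 °C, 1 bpm) emulating tonic level wander, embedded
events, unannotated *distractor* transients, and sensor artifacts
(dropouts, spikes, flat-lines, out-of-range excursions). Event
morphologies are idealized so each detector measures the embedded
magnitude exactly at zero noise: EDRs are linear ramps with exponential
recovery, temperature events half-cosine monotone excursions with slow
relaxation, heart-rate events triangular excursions. Annotations are
placed at each event's feature-maximal time (ramp end, or apex), so
detections and annotations align under the ±10 s tolerance.

Heart-rate excursions carry a direction (acceleration or deceleration),
and the bundled `reference_session("hr_responder")` alternates them.
This is not cosmetic: between two same-direction excursions, the deepest
point of the return to baseline is itself a local extremum whose
topographic prominence equals the excursion height, so an all-ascending
session would contain unmatchable deceleration detections that no
threshold can remove. Real heart-rate data contains both directions;
the generator reflects that.

The three `reference_session()` archetypes place four mono-modal events
(magnitudes 0.24 µS in 10 s, 30 bpm over 20 s, 0.02 °C over 25 s —
magnitudes representative of individually tailored thresholds) on a
fixed 75 s schedule in a 360 s session, with three weaker distractors
(0.12 µS, 18 bpm, 0.012 °C) between them, strong enough to fool the
default thresholds but separable by tailoring. The temperature archetype
uses reduced drift (0.003 °C amplitude) and noise so that 0.02 °C
excursions, not session-long wander, carry the signal — at the default
drift a 25 s window sees ~0.026 °C of pure drift, which would swamp the
events; scientifically this emulates a thermally stable recording
environment.

What the generator does **not** emulate: pulse-level photoplethysmography
waveforms and respiratory sinus arrhythmia (heart rate is a smooth rate
series), motion-correlated multi-channel artifacts, skin-contact drying
trends, or any coupling between the two members of a dyad. Passing tests
therefore demonstrate that the pipeline recovers events of the stated
shapes under realistic noise — not that it reaches any particular
accuracy on real dyad recordings, which depend on human feedback loops
that desk-scale synthetic data cannot reproduce. The acceptance suite's
70%-precision check is a property-based stand-in for the field result at
the same headline rate, run over 20 seeded archetype sessions
(precision averaged across sessions, each at its configured event cap).

## Numerical choices and degenerate inputs

* Problem sizes: tests use 30–600 s sessions (up to 9 000 raw samples);
  tailoring searches a few hundred effective candidates per session
  after de-duplicating threshold combinations made irrelevant by
  zero-weight channels. A 45-minute session preprocesses and tailors in
  seconds.
* `smooth.spline` and the exact band-matrix (Reinsch) solution of the
  same criterion agree to ~10⁻³ relative; the p → 0 and p → 1 limits are
  handled explicitly (least-squares line; interpolation).
* Sessions shorter than one moving-average window yield an empty 2 Hz
  series with a warning; fewer than four 2 Hz samples skip the spline.
* An all-flagged channel is an error — there is nothing to interpolate
  from.
* A single-step SQI series has undefined σ; the mask treats it as valid.
* Equal scores at selection and equal distances at matching are broken
  toward earlier times, making every pipeline stage deterministic;
  generation is reproducible bit-for-bit from its seed.

## Known limitations

* SQI thresholds are fixed rules, not learned; the µ − σ mask adapts to
  the session but not to the individual.
* Scores are per-step; no integration over a window, no multivariate
  cross-channel features, no heart-rate-variability features, and no
  valence (positive vs negative) classification — the last is known to
  be poorly determined by these channels alone.
* Precision-at-N is blind to recall except through explicit missed-moment
  feedback, mirroring the interview workflow it automates.
* The one-Euro stage at 2 Hz is effectively inert at its published
  parameters (see above).
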