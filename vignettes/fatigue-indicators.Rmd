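---
title: "Eye closure-associated fatigue indicators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye closure-associated fatigue indicators: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perclosr)
```

`perclosr` implements the analysis pipeline of a camera-based driver-fatigue
monitor. This vignette documents the model behind each stage, the tunable
parameters and why their defaults are what they are, what the synthetic
generators do and do not emulate, and the design choices made where more
than one defensible option existed.

## Eye-state classification by template matching

The classifier assumes a monochrome facial video (60 fps by default) and an
external landmark provider that returns the two eye-center pixel
coordinates per frame, or a not-found signal. Around each center a
fixed-size patch is cut and compared against K stored open-eye template
pairs using the Pearson-type normalized correlation coefficient. Three
choices deserve a note:

* **Clamping.** The correlation is clamped to [0, 1]: an anti-correlated
  patch carries no evidence of an open eye, so the negative branch is
  treated as "no match" rather than kept signed. This also keeps the score
  on the conventional template-matching scale.
* **Sequential acceptance.** Templates are tried in order and the search
  stops at the first score at or above the threshold. This is
  behaviourally identical to testing `max(scores) >= threshold` (a property
  the test suite verifies by exhaustive enumeration), but mirrors how such
  matchers are run in production, where early stopping saves work.
* **Open-eye templates only.** Open eyes are the more characteristic
  appearance; eye closure is detected as the *failure* of every open-eye
  template, not by matching closed-eye exemplars. A partially closed eye
  that still matches an open template at the threshold counts as open —
  the match threshold, not a separate lid-coverage estimator, is what
  operationalizes "at least 75% pupil coverage" for closure.

The acceptance threshold defaults to 0.68 (match score, unitless in
[0, 1]); K defaults to 3 pairs, trading robustness against per-frame cost.
Both eyes must be closed for the frame to count as closed. When exactly one
eye is unclassified, the combined state is *missing*, not closed: closure
requires positive evidence from both eyes, and fabricating it from one
would bias the frame counts. Unclassified frames are never dropped; they
can be resolved by an override file (inclusive frame ranges with a target
state, later rows winning on overlap), replacing interactive manual
correction with an auditable artifact.

The template patch size is not a principled constant; it is taken from the
calibration rectangles, which the user (or the synthetic renderer) chooses
to cover the eye region. Patches that extend past the frame edge are
zero-padded and flagged rather than rejected, so a driver near the image
border degrades gracefully. A patch with zero intensity variance (possible
with heavy padding or sensor saturation) is uninformative; such frames
become unclassified rather than being forced into either state.

## Event segmentation and blink exclusion

A closure event ("cluster") is a maximal run of combined-closed frames.
Runs are split — never bridged — by unclassified gaps, and both fragments
are marked `truncated`, as are events touching the series boundaries: the
true extent of those events is unknown, and inventing closed frames would
bias every downstream duration.

Blink exclusion uses a duration cutoff of 200 ms. The millisecond value is
primary; the frame cutoff is derived as `round(200 * fps / 1000)` — 12
frames at 60 fps, 6 at 30 fps — so the boundary stays physiologically
meaningful across frame rates. An event of at most the cutoff is a blink;
strictly longer events are *qualifying* closures, the only ones entering
the indicators. The boundary semantics ("200 ms or less is excluded",
"longer than 200 ms qualifies") are tested on both sides of 12 frames.

## Windowed indicators

Indicators are computed over consecutive, non-overlapping 30-s windows
(1800 frames at 60 fps), half-open in frames. Overlapping windows would
smooth the traces but change the meaning of the per-window count
indicators, and the tiling interpretation matches how these indicators are
conventionally reported.

Within a window with `n` qualifying clusters covering `N_closed` frames of
its `N` total frames:

* `PERCLOS = N_closed / N`, a time fraction in [0, 1];
* `ECD = N_closed / n` frames (missing when `n = 0` — a mean over an empty
  set is undefined, and reporting 0 would fake an impossibly short
  closure; summaries skip missing windows and report the count used);
* `FEC = n`.

Events are **frame-split** for PERCLOS (it is a time fraction, so each
window gets the frames that fall inside it) but **start-assigned with
their full duration** for ECD and FEC (they are event-level statistics, and
splitting an 800-ms closure into two 400-ms halves would corrupt the
duration distribution). The two conventions are reconciled in the test
suite by a brute-force recomputation from the raw mask.

Unclassified frames stay in the denominator — `N` is the fixed window
length — and are reported per window; windows with more than 10%
unclassified frames (configurable) are flagged low-confidence. A trailing
partial window is reported with its true frame count and flagged
incomplete; session summaries use complete windows only.

Fatigue flags are strict: PERCLOS > 0.15, ECD > 400 ms (24 frames at
60 fps), FEC > 5 per window. Values exactly at a threshold do not flag.
The session summary takes arithmetic means of the first `min(10, k)` and
last `min(10, k)` complete windows — five minutes at each end of a drive —
matching a pre-test/post-test design where a questionnaire brackets the
session.

## Synthetic generators

The aperture generator emulates, per session: blinks as a Poisson process
(default 15–20 per minute) with truncated-normal durations in (0, 200] ms;
qualifying closures as a rarer Poisson process whose durations are 200 ms
plus a lognormal excess (heavy-tailed, as drowsy closures are); and a
linear *drift* that multiplies the closure rate and duration excess from
1 at the session start to a configured factor at the end, emulating
fatigue building up during a monotonous drive. Events are placed with at
least one open frame between them, by bounded rejection, so ground-truth
events map one-to-one onto closed runs — the generator/analyzer closure
property the tests rely on. Frames below 0.25 of full opening are closed,
echoing the 75%-lid-coverage convention; the aperture values themselves
are drawn away from the boundary (open frames in [0.85, 1], event frames
in [0.02, 0.18]) so thresholding is unambiguous.

The two presets were fixed once, before any end-to-end runs, to sit in the
bands typical of rested and drowsy drivers: `"rested"` (5.5 closures/min,
~280 ms mean duration, drift 1.8) targets a mean session PERCLOS around
0.03–0.07 and 3–4 qualifying closures per window; `"drowsy"` (12/min,
~380 ms, drift 1.8) targets 0.08–0.15 and 7–9 per window, with the last
windows approaching the fatigue thresholds. These are plausibility
anchors, not fitted quantities.

The renderer draws two dark ellipses whose vertical opening scales with
the aperture, a persistent lid line, and Gaussian pixel noise (sd 0.02 on
a [0, 1] intensity scale), and returns a perfect landmark provider. It
emulates exactly what the classifier consumes — local contrast around the
eye centers — and nothing else: no head pose, no illumination drift, no
landmark jitter, no eyelash/eyebrow structure, no specular IR reflections.
A clean pass of the rendered end-to-end test therefore shows that the
classification, segmentation and indicator logic is correct, not that the
matcher would survive real in-cab footage; the manual-override path and
the unclassified-frame bookkeeping exist precisely because real landmark
engines fail in ways the synthetic provider does not.

The subjective-fatigue simulator draws one row per subject × condition
(rested/drowsy) × occasion (pre/post) as
`fss = intercept + time_slope * occasion + indicator_slope * indicator +
u_subject + u_condition + residual`, with mean-zero normal random
intercepts at the subject and condition-within-subject levels. Defaults
(variances 237/217/178, intercept 30) echo the magnitudes seen in
moderate-sized driver studies on a raw questionnaire-score scale.

## Statistical evaluation

**Paired comparisons.** The paired t-test is delegated to `stats::t.test`;
the dependent-samples Cohen's d is computed in-package. Several d variants
circulate for paired designs; the default here is the correlation-corrected
repeated-measures form `d_rm = mean(diff) * sqrt(2 (1 - r)) / sd(diff)`,
which reduces to the classical between-forms scale when the pre/post
correlation `r` is 0 and is the common recommendation when the correlation
is substantial. The `"av"` (mean difference over averaged SDs) and `"z"`
(standardized difference score) forms are selectable, because reported
effect sizes in this literature mix all three. When all differences are
zero the test degenerates to t = 0, d = 0, p = 1; a constant nonzero
difference is an error, not a silent infinity.

**ROC.** AUC uses the rank (Mann–Whitney) formula, ties counting one half
— exactly the pair-counting definition, which the tests verify
exhaustively at small n. The bootstrap CI resamples within classes
(stratified), so both classes survive every replicate, and takes
percentile endpoints. The optimal threshold maximizes Youden's J over
midpoints between adjacent distinct scores (with ±Inf sentinels); on ties
the first maximum wins, which with the midpoint convention is
deterministic. Higher scores indicate the positive class; callers with
inverted scales negate their scores.

**Three-level models.** The models are
`fss_s ~ 1 [+ occasion] [+ indicator] + (1 | subject / condition)`,
fitted by maximum likelihood (not REML, so likelihood-ratio comparisons of
fixed effects are valid) via `lme4::lmer` with its default deterministic
optimizer. The indicator is z-standardized over all rows before entry, so
its slope is per indicator-SD. Convergence messages are surfaced in an
honest `converged` flag rather than swallowed. Derived quantities are
implemented in-package on the fit record:

* ICC at level k = `var_k / (var_subject + var_condition + var_residual)`;
* marginal R² = `var_f / (var_f + var_subject + var_condition +
  var_residual)` and conditional R² adding the random-intercept variances
  to the numerator, with `var_f` the variance of the fixed-effect linear
  predictor;
* delta R² at level k = `(var_ref,k − var_new,k) / var_ref,k`, reported
  signed (a variance *increase* upon adding a predictor is informative and
  is not clipped), and missing where the reference variance is 0;
* the comparison table reports AIC, −2 log L, df, and the LRT χ² of each
  model against its designated reference with `p = P(χ²_Δdf ≥ observed)`.
  On one published comparison table, a χ² of 5.673 at Δdf = 1 is
  flagged "p < 0.01" in the table footnote while the computed p is 0.017;
  `compare_models()` always reports the computed p.

`model_fit()` is exported so a comparison table can be rebuilt from
printed −2 log L values without access to the raw data; variance
components may then be absent and only the LRT arithmetic is available.

Variance-component p-values are deliberately not computed: their null
hypothesis sits on the boundary of the parameter space and the usual Wald
machinery does not apply.

## Problem sizes and numerical tolerances

The test suite runs the oracle-equivalence sweep on 1,000–2,000 random
masks of 1,800–5,400 frames, the rendered end-to-end check on one full
1,800-frame window, and the slope-recovery study on 100 replicates of 200
subjects (800 rows each); these sizes give Monte-Carlo error comfortably
below the asserted margins while keeping a full run around a minute and a
half. Score comparisons against the direct correlation formula use 1e−10;
indicator comparisons against the brute-force oracle are exact
(`all.equal` at machine precision), because both sides are integer
arithmetic divided by fixed denominators.

## Known limitations

* No face/landmark detection is included; the landmark provider is an
  injected interface, and the package's accuracy claims are conditional on
  its quality.
* MP4 input is not read directly; frame sequences are consumed as PNG
  directories or in-memory matrix lists.
* The renderer's simplicity means rendered-video tests validate pipeline
  logic, not real-world robustness (see above).
* Fatigue thresholds are fixed conventions, not calibrated decision
  boundaries; with eight-driver-scale data the indicators' critical values
  cannot be estimated reliably, which is why they are exposed as
  configuration.
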