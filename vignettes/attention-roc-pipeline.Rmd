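---
title: "Quantifying learned attention-related modulation in collicular spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying learned attention-related modulation in collicular spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnroc)
```

## The scientific problem

Head-fixed mice running on a wheel progress through a four-epoch visual
trial: pink **noise**, a lateralized Gabor **cue**, a **2-patch** delay in
which a second Gabor appears in the opposite hemifield, and a **change**
epoch in which the cued patch may tilt by 9–30 degrees. Depending on the
reward contingencies a mouse has learned, the same stimulus sequence carries
very different behavioral relevance: passively viewing animals lick early in
the trial for automatically delivered rewards (*naive*), animals trained on
stimulus–reward association ramp their licking up through the trial
(*intermediate*), and animals trained to detect the orientation change lick
abruptly after it (*expert*).

`attnroc` implements the quantification chain used to ask whether
attention-related modulation of superior colliculus (SC) spiking depends on
this learned relevance: epoch-windowed ROC discriminability of spike counts,
bootstrap and permutation inference, random-intercept group comparison,
lick-based session classification, behavioral scoring, and saccade controls
— together with a synthetic-session generator that provides ground truth
for validating every stage. Recorded data for this paradigm are not publicly
deposited, so the generator is a first-class module: it defines the study
conditions under which the pipeline's statistical properties are tested.

## The discriminability measure

For two sets of spike counts, the area under the ROC curve (AROC) is the
probability that a randomly drawn *signal* count exceeds a randomly drawn
*noise* count, with ties given half credit:

$$\mathrm{AROC} = \frac{1}{n_s n_n} \sum_{i,j}
  \left[ \mathbf{1}(s_i > n_j) + \tfrac12 \mathbf{1}(s_i = n_j) \right],$$

computed internally via midranks (the normalized Mann–Whitney U), which is
identical to the pairwise definition. 0.5 means the distributions are
indistinguishable. Three epoch definitions are fixed in `epoch_spec()`:

* **cue onset** — response rates 40–140 ms after cue onset vs baseline
  −100–0 ms before it, on contralateral-cue change trials;
* **delay spatial** — end-of-delay rates (−200–0 ms before change onset) on
  contralateral- vs ipsilateral-cue trials;
* **change onset** — 40–140 ms after vs −100–0 ms before change onset, on
  contralateral-cue change trials, stratified by tilt category
  (large = 30°, medium = 15/20°, small = 9/12°).

All windows are half-open `[a, b)` in milliseconds, so 20 ms PSTH bins
partition a range with no double counting; the underlying task literature is
silent on boundary handling, and half-open intervals are the convention that
makes count conservation exact. No-change catch trials are excluded from all
discriminability analyses, and all trial outcomes are pooled (hits and
misses are only well defined for expert sessions). Whether the within-trial
epochs (cue/change) should pool both cue sides is not specified by the task
description; the package defaults to contralateral-only — the stimulus in
the recorded hemifield — with a `cue_side_filter` switch.

Per-unit uncertainty uses the percentile bootstrap: signal and noise trial
sets are resampled independently with replacement, preserving their sizes
(1,000 replicates; 2.5/97.5 percentiles). A unit is *positively* or
*negatively* discriminating when its 95% CI lies entirely above or below
0.5. Units with fewer than 5 trials per set (configurable) are excluded;
the resampling unit is a design choice — the source analyses do not state
it — and per-set resampling is the variant that keeps the two distributions
independent under the null.

## Group comparison: dual inference

Differences in AROC between performance levels are assessed two ways, and a
difference only counts when **both** tests pass at α = 0.05:

1. a linear mixed model `AROC ~ level + (1 | session)` with a binary level
   effect and a random session intercept, testing the fixed effect with a
   Wald z-test (REML fit via `lme4`);
2. a session-level permutation test: the difference of group medians of
   within-session mean AROC, against a null built by shuffling level labels
   across sessions (10,000 shuffles by default, two-sided). When the number
   of distinct label assignments is at most the permutation budget the test
   enumerates them all and reports the exact fraction; otherwise the
   Monte-Carlo estimate uses the add-one correction (1 + k)/(B + 1), which
   guarantees validity and never returns zero.

When each session contributes a single unit the random intercept is
confounded with the residual; the model then properly reduces to ordinary
least squares, which the package does explicitly (with a message) rather
than forcing an unidentifiable fit. Within-session summary (mean vs median)
is configurable; the mean is the default. Pairwise comparisons
(naive–intermediate, intermediate–expert, naive–expert) are run
independently with no multiplicity adjustment, mirroring the structure of
the original analysis.

A property of this dual rule worth knowing: the two p-values are strongly
positively correlated (both are driven by the same between-group
difference; one uses the mean of session means, the other the median), so
the joint null rate per comparison is close to the single-test α of 5%,
not to the α² ≈ 0.25% that independence would give. Package simulations
(see the acceptance tests) measure a joint null rate of roughly 3–4% per
comparison; across a full comparisons grid, occasional joint false
positives under a global null are therefore expected, exactly as for any
single test at α = 0.05.

## Session classification from lick patterns

Non-naive sessions are assigned *intermediate* or *expert* from their licks
alone. Each session is summarized by a change-aligned lick time course
(−3,000 to +1,500 ms in 100 ms bins, averaged over change trials and
normalized to unit sum, so shape rather than overall rate drives the
classification; the alignment and binning are package choices, exposed in
the configuration). The vectors are embedded in two dimensions and split by
2-means (fixed seed, 10 restarts); the cluster whose sessions carry more
lick mass inside the task's own 300–800 ms response window is labeled
expert, which makes the cluster-to-level mapping objective rather than
visual.

The embedding is classical multidimensional scaling of Euclidean distances
between the lick vectors. It is deterministic, preserves the two-archetype
geometry faithfully (the archetypes differ along a dominant direction of
variance), and in the package's validation recovers generating archetypes
with ≥ 95% accuracy on 60 synthetic sessions — the package's analogue of
the session-versus-cohort agreement reported for the real data, which is
not reproducible here. A degenerate split — all sessions from one archetype
— is detected by a gap statistic (closest cross-cluster distance relative
to the median within-cluster nearest-neighbour distance, flagged below 3)
and raises a warning rather than silently producing two spurious levels.

## Behavioral scoring

A change trial is a *hit* if a lick falls in the 300–800 ms window after
change onset; a no-change trial is a *false alarm* if the mouse licks in
the equivalent window. Under the expert task rules, licks earlier than the
response window (including before the change) abort the trial, since they
cannot be responses to the change. Sensitivity is
`d' = z(HR) − z(FAR)` with the log-linear correction (0.5 added to counts,
1 to denominators) so it stays finite at extreme rates; for cohorts without
catch trials, false alarms — and hence d′ — are undefined and reported as
`NA`. Reaction time is the first in-window lick on hit trials, summarized
by the median (the summary statistic is not specified in the source
analyses; the median is robust to the occasional long-latency lick).
Cued-versus-probe session comparisons use a two-sided Wilcoxon signed-rank
test, exact by sign-flip enumeration up to 16 non-zero pairs (which remains
exact under ties, where the large-sample approximation would be used
otherwise).

## Saccade detection and controls

Eye position is consumed as a calibrated 240 Hz two-dimensional trace in
degrees. Speed is the magnitude of the central-difference velocity, with a
3-sample median prefilter when the trace is noisy (the thresholds are
stated in the source, the differentiation scheme is not). Candidate epochs
are maximal runs with speed > 50°/s; each run is extended outward to the
surrounding low-speed flanks (< 10°/s) and kept if the suprathreshold run
lasts > 15 ms and the net displacement between the bounding stationary
samples exceeds 2° — all strict inequalities, as stated. Amplitude is
straight-line displacement, not path length. On clean synthetic traces the
detector attains precision = recall = 1 with amplitude errors below 0.01°.
Event-aligned saccade probability is the per-bin fraction of trials with a
saccade onset in the bin, and `saccade_free_mask()` flags trials with no
saccade onset in the union of an epoch's baseline and response windows so
any analysis can be repeated saccade-free. Whether "saccade-free" should
exclude whole trials or only analysis windows is ambiguous in the source;
windows-only is implemented (and is the stricter reading for the analyses
actually affected).

## The synthetic-session generator

The generator is the package's ground truth, not a fixture: every
statistical property above is tested against sessions whose modulation is
known exactly.

* **Timeline.** Epoch durations are drawn uniformly from the task's printed
  time ranges (noise 0.2–0.3 s, cue 0.36–1.55 s, 2-patch 0.84–3.6 s); the
  wheel-distance mechanism that generates those ranges in the real task
  adds nothing testable and is not modeled. Cue sides alternate in
  interleaved blocks; cohorts with catch trials get a change on a random
  half of trials; the intermediate cohort never sees catch trials.
* **Spiking.** Units are inhomogeneous Poisson processes sampled by
  thinning. The event-locked rate is baseline plus causal
  difference-of-exponentials transients at cue and change onset (latency
  40 ms, rise 10 ms, decay 60 ms — placing the transient inside the
  40–140 ms analysis window) plus a sustained contralateral bias during the
  delay. Change-transient amplitude scales linearly with tilt/30. A
  level-by-layer gain table encodes the qualitative target pattern —
  superficial cue responses at all levels growing with training; deep cue,
  delay, and change modulation absent in the naive state — as synthetic
  ground truth, not as estimates of the real data. Log-normal per-session
  (SD 0.1) and per-unit (SD 0.15) amplitude jitter creates the
  between-session variance structure the mixed model exists to handle.
* **Licks.** Three intensity archetypes: an early burst with fast decay and
  a 0.05 Hz tail (naive; nominal hit rate ≈ 0.03), a linear ramp to
  ~1.8 Hz with a reward-locked bump after the change (intermediate; hit
  rate ≈ 0.66), and a near-silent baseline with a Gaussian transient at
  450 ± 80 ms after the change (expert; hit rate ≈ 0.83 with a few percent
  anticipatory aborts). Published lick-rate axes are not available, so the
  absolute intensities are free parameters chosen to land the cohorts'
  published hit rates; probe trials scale the expert transient by 0.84 to
  reproduce the published cued-versus-probe hit-rate gap direction.
* **Eye traces.** 240 Hz positions with additive Gaussian noise and sparse
  scheduled saccades, each a smoothstep displacement of given amplitude and
  duration (peak speed `1.5 × amplitude / duration`, comfortably above the
  50°/s criterion for all realistic parameters).

A single global seed expands into independent per-stream seeds (timeline,
licks, per-unit spikes, eye, bootstrap, permutation) through a small
multiplicative hash, so any stream can be reproduced in isolation and
identical seeds give bit-identical sessions.

What the generator does **not** emulate: biophysical spiking dynamics
(refractoriness, bursting, adaptation), correlated variability between
simultaneously recorded units, slow drifts in excitability, wheel-speed
coupling, and pupil dynamics. Passing tests therefore demonstrate that the
analysis chain is correct and calibrated for independent Poisson units with
the stated modulation structure — they do not certify behavior on real
recordings with correlated noise.

## Validation scale and numerical choices

The acceptance suite runs the chain at desk scale: AROC oracle equivalence
on 1,000 random count-vector pairs; the Gaussian closed form
$\Phi(\delta/\sqrt2)$ at n = 5,000 per side; bootstrap-CI significance
calibration on 500 null units of 100 trials; permutation exactness against
full enumeration and type-I calibration over 1,000 null datasets at 2,000
permutations (scaled down from the 10,000 used for real analyses); mixed
model recovery over 200 replicates of a 40-session × 20-unit design
(β₁ = 0.05, σᵤ = 0.02, σₑ = 0.10); archetype recovery on 60 sessions; 100
clean eye traces; and an end-to-end two-cohort study of 8 + 8 sessions ×
8 units × 200 trials. These sizes are the package's validation conditions,
chosen so each check has adequate statistical resolution for its stated
tolerance.

Numerical details worth recording: AROC uses midranks, so tie handling is
exact; bootstrap percentiles use the default quantile definition; window
boundaries round event-relative lick times to sub-microsecond before
comparison so that boundary semantics are stable against floating-point
representation of event times; thinning requires an explicit rate ceiling
and rejects rate functions that exceed it; zero-baseline-SD z-scores are
reported as signed infinity and ordered last; degenerate bootstrap CIs
(constant data) collapse to a point, as they should.

## Known limitations

* The dual-test joint null rate is ~α, not ~α² (see above); users scanning
  a full comparisons grid under a global null should expect isolated joint
  positives at roughly the single-test rate.
* The Wald z-test on the mixed-model fixed effect is mildly anti-conservative
  with few sessions; the permutation companion is exact and is the
  safeguard in the joint rule.
* The classifier requires at least 4 sessions and two genuinely distinct
  lick patterns; single-archetype studies are flagged, not refused.
* The generator's amplitudes are synthetic ground truth. Population AROC
  medians produced by the pipeline depend on them and are not estimates of
  the published medians, which derive from undeposited recordings.
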