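---
title: "Quantifying dyadic head-movement synchrony: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic head-movement synchrony: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

During a face-to-face (or video-call) conversation, two people's head
movements become temporally coordinated: one partner nods, the other follows
within a fraction of a second. This *interpersonal synchrony* is a marker of
social engagement, and its disruption is of clinical interest in the
psychosis spectrum, where reduced nonverbal coordination has been reported
repeatedly. dyadsync implements a complete, testable pipeline for measuring
head-movement synchrony between a participant and an assessor from
pose-tracker output: per-frame nose-landmark trajectories of both people in
a side-by-side recording, typically at 25 Hz. Only the vertical (y-axis)
coordinate is analyzed — vertical movements capture head nods, whereas
horizontal movements are contaminated by assessors reading from their
screens.

The package contains no video processing. Its input contract starts where a
pose tracker (e.g. a 17-keypoint whole-body model) ends: a delimited table
of `(frame, person, landmark, x, y)` rows.

## Preprocessing

Each person's raw vertical nose trajectory is cleaned in a fixed order:

1. **Outlier removal** by the scaled-MAD rule: a frame is an outlier when
   its absolute deviation from the series median exceeds
   $k \times 1.4826 \times \mathrm{MAD}$, with $k = 3$. The constant 1.4826
   makes the MAD a consistent estimate of the SD under normality. When the
   MAD is zero (at least half the frames identical, e.g. a frozen tracker),
   nothing is flagged — the robust spread estimate carries no information,
   and we prefer to pass the series through rather than delete it wholesale.
2. **Linear interpolation** of removed and missing frames between the
   nearest valid neighbours. Leading and trailing gaps are filled with the
   nearest valid value: constant extrapolation invents no trend beyond the
   data.
3. **Median filtering** with a centered 15-frame window (0.6 s at 25 Hz),
   which suppresses residual tracker jitter while preserving nod edges. At
   the series boundaries the window is truncated to the available samples
   rather than padded — padding would fabricate data.
4. **Z-normalization** (mean 0, SD 1; sample SD with denominator $n-1$ —
   at the 15,000-frame scale of a 10-minute recording the distinction from
   $n$ is numerically irrelevant, but the convention is fixed so tests can
   be exact). A constant series cannot be normalized; such a dyad is
   excluded and logged rather than silently propagated.

Total movement per person is also computed here. The natural reading of
"summing absolute position values" is $\sum_t |v_t|$ on the normalized
series (`abs_position`, the default); because that quantity is ambiguous for
a centered series, the path length $\sum_t |v_{t+1} - v_t|$
(`abs_displacement`) is implemented alongside, and neither is asserted to be
the only correct summary. Whether the sum is taken before or after
normalization is configurable by preprocessing with `normalize = FALSE`;
the default pipeline computes it after.

## Windowed cross-correlation, peak picking, strength and delay

The synchrony measure follows the classic windowed cross-correlation (WCC)
construction. The two cleaned series are split into overlapping windows of
90 frames (3.6 s) with 50% overlap (45-frame stride). Within each window
the Pearson correlation between the participant's values at time $t$ and
the assessor's values at $t - \ell$ is computed for every lag
$\ell = -50, \dots, +50$ frames (±2 s at 25 Hz), using the overlapping part
of the window (at the extreme lag, 40 of 90 frames). **Positive lag means
the assessor's movement is ahead of the participant's** — the participant
follows.

Each correlation is Fisher-Z transformed ($z = \operatorname{artanh} r$)
before any aggregation; this is what allows reported strengths to exceed 1
(for $r > \tanh 1 \approx 0.76$). Correlations within $10^{-12}$ of ±1
(e.g. from degenerate identical windows) are clipped to keep $z$ finite,
and the clip count is recorded.

Per window, a peak-picking step takes the **maximum of the signed**
Fisher-Z values over lags — in-phase coordination is the target signal, and
summarizing signed maxima is what makes cohort strengths of ≈1.2 Fisher-Z
attainable; maximizing $|z|$ would conflate in-phase and anti-phase
coordination. Exact ties are broken toward the smallest absolute lag, then
toward the negative lag; both rules are stated so tests can be exact, and
tie cells are vanishingly rare off the degenerate cases. A peak sitting on
the ±2 s boundary is retained but flagged, since its true lag may lie
outside the searched range. Windows in which either segment has zero
variance have no defined correlation; they are marked invalid and excluded
from the medians (and counted, so a dyad with a frozen tracker segment is
visible).

A dyad is then summarized by:

* **strength** — the median over valid windows of the peak Fisher-Z
  correlation;
* **delay** — the median over valid windows of the peak lag, in seconds,
  signed as above.

Even-count medians use the usual midpoint convention. Trailing partial
windows are dropped rather than padded: a short tail window would
contribute a noisier correlation. Alternative window widths (5 s, 7 s) are
a one-argument change (`wcc_params(window_frames = 125)`), and on synthetic
cohorts they rank dyads consistently with the 3.6 s configuration
(rank correlation > 0.8 in the test suite).

The window/lag computation is implemented in compiled code (a direct
two-pass-free sums formulation per window-lag cell); the test suite pins it
cell-by-cell, at $10^{-10}$, to a naive R triple loop written with an
independent centered-deviations Pearson formula.

## The pseudosynchrony null

Whether an observed strength exceeds chance is judged against a
*pseudosynchrony* null: the participant's cleaned series is partitioned
into consecutive 90-frame segments (one WCC window each; a shorter
remainder stays in place), the segment order is permuted uniformly at
random, and the entire strength computation is repeated; 100 such
surrogates per dyad give a per-dyad null distribution. Shuffling one
partner destroys the interpersonal alignment exactly once while preserving
each person's own movement structure; shuffling the assessor or both is
available for sensitivity analyses. The per-dyad pseudo summary is the mean
of the surrogate strengths, which is the natural paired counterpart for the
cohort-level dependent t-test of genuine versus pseudo strength.

### A known bias, quantified

Segment shuffling is not an exact null for smooth signals, and the package
does not pretend otherwise. Analysis windows that straddle a splice between
two shuffled segments contain two mutually independent smooth halves;
the peak-over-lags correlation of such a window is stochastically smaller
than that of an intact window (fewer effective degrees of freedom of smooth
chance alignment). The surrogate null is therefore shifted slightly
downward — on synthetic uncoupled dyads the shift is ≈0.02 Fisher-Z, and
it grows in *relative* importance with recording length because the null's
spread shrinks while the splice shift does not. Concretely, in the test
suite an uncoupled dyad's genuine strength exceeds its own null's 95th
percentile in roughly 13% of dyads at 60 s (and more at 600 s) rather than
the nominal 5%; a diagnostic comparing a single-splice rotation against the
full shuffle confirms the splice count drives the shift. The corresponding
calibration test is deliberately left failing rather than widened: it
documents a real property of splice-based pseudosynchrony under smooth,
autocorrelated motion. Cohort-level genuine-vs-pseudo comparisons remain
directionally valid, but a small part of any genuine−pseudo difference is
attributable to this splice artifact, and per-dyad "significance against
the null" should not be read as a calibrated 5% test.

## The synthetic-data generator

No clinical recordings ship with the package; every stage is exercised by a
generator with known ground truth.

A dyad is simulated as a leader–follower pair: the leader moves as
standardized AR(1) noise ($\varphi = 0.95$, autocorrelation time ≈20
frames) smoothed by a 5-frame moving average — slow, drifting motion with
nod-scale structure — and the follower is

$$\text{follower}(t) = c \cdot \text{leader}(t - L) + \sqrt{1 - c^2}\,\eta(t),$$

with coupling $c \in [0,1]$, lag $L$ in frames, and $\eta$ an independent
noise series of the same character; both series are standardized. With the
participant as follower (the default), a positive $L$ makes the assessor
lead, so the pipeline should report delay $+L/f_s$ — and does, within one
frame, for $c \ge 0.7$. What the generator does *not* emulate: tracker
dropouts and spikes (tested separately in preprocessing), nonstationary
engagement over the interview, turn-taking structure, and any asymmetry
between nodding and stillness; passing recovery tests here demonstrates
correctness of the estimator, not validity on any particular clinical
population.

The measured strength is a *nonlinear* function of coupling: below
$c \approx 0.5$ the chance peak floor (≈1.17 Fisher-Z for these smoothness
settings) dominates and the map is nearly flat; above it the map rises
roughly linearly. The cohort generator therefore calibrates itself
empirically: `calibrate_strength_map()` runs the full pipeline over a
coupling grid (19 values × 8 dyads at the cohort's geometry) and stores
the isotonic mean response and the within-coupling SD of measured strength.

Cohorts mirror a three-group clinical design: 30 HC, 36 SUB and 50 CHR
dyads nested in 32 assessors. Group mean couplings default to HC 0.65,
SUB 0.62, CHR 0.57: placed in the responsive region of the map, with the
HC−CHR contrast sized so that the induced mean strength deficit is
≈0.05 Fisher-Z, the magnitude reported for the CHR effect in the clinical
literature this design emulates. Dyad-level coupling heterogeneity is
SD 0.08. The assessor effect is a random intercept *on the coupling scale*;
because the requested intraclass correlation (default 0.141) is defined on
the *strength* scale, the generator solves for the intercept SD by
propagating the latent effects through the calibrated response map
(common-random-numbers Monte Carlo inside a root finder). This makes the
ICC-recovery simulation well-posed despite the nonlinearity: with the
defaults, the REML-fitted ICC has its median within a few points of 0.141
over 100 replicate cohorts.

Per-dyad true lags are drawn as rounded $N(0, 5)$ frames. Synthetic symptom
and functioning scores are linear in the latent truth plus unit noise —
social anhedonia rises with following delay (slope 2 per second on top of
group baselines), social/role functioning rise with coupling — with
arbitrary, clearly synthetic slopes; they exist to exercise the correlation
and FDR code paths with known sign structure, not to model any instrument.

## Cohort statistics

The statistical layer mirrors the analysis such a study reports:

* one-way ANOVA of total movement across the three groups;
* a dependent t-test of genuine versus pseudo strength (degenerate
  zero-variance difference vectors are flagged, with a relative tolerance
  of $10^{-10}$ deciding "constant");
* linear mixed models for strength and for delay: fixed effects of group
  (reference HC), participant sex, assessor sex and their interaction, and
  a random intercept per assessor. Fitting is REML (lme4), p values use
  Satterthwaite degrees of freedom (lmerTest), confidence intervals are
  Wald — choices documented as package conventions, since contract-level
  equivalents exist. The ICC is
  $\sigma^2_{\text{assessor}} / (\sigma^2_{\text{assessor}} + \sigma^2_{\text{resid}})$;
  a singular fit is reported with the ICC at its 0 boundary and flagged,
  not hidden. Post hoc pairwise group contrasts come from estimated
  marginal means with BH-adjusted p values;
* two-way group × dyad-type ANOVAs with Type-II sums of squares (the
  design is unbalanced by construction; Type-II is invariant to cell-size
  imbalance for the main-effect hypotheses) and generalized eta-squared
  effect sizes;
* Pearson correlations of strength/delay with score columns under
  pairwise-complete deletion, with Benjamini–Hochberg adjustment applied
  per analysis family (the symptom family and the functioning family are
  adjusted separately, mirroring how such results are reported; the family
  is whatever column set the caller passes in one call). Correlations with
  fewer than 4 complete pairs or a constant column are flagged and kept out
  of the adjusted family.

## Numerical conventions and problem sizes

* Fisher-Z clipping at $|r| = 1 - 10^{-12}$; `atanh` thereafter.
* Tie-breaking and boundary flagging as described above; all medians use
  the midpoint convention for even counts.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state; identical seeds reproduce surrogate nulls bit-for-bit.
* Simulation studies in the test suite and the acceptance script use 60 s
  dyads for per-dyad properties (lag recovery, surrogate calibration) and
  120 s dyads for 116-dyad cohort replicates — sizes at which per-dyad
  medians are stable (≈30 and ≈65 windows) while hundreds of full-pipeline
  replicates stay cheap. The generator's own default remains the
  10-minute (600 s) recording the design emulates.

## Known limitations

* The pseudosynchrony splice bias discussed above.
* Strength is a chance-floor-plus-signal quantity: differences in
  *smoothness* between dyads move the floor and hence measured strength,
  independent of true coupling. Comparing cohorts preprocessed differently
  is therefore not meaningful.
* The mixed model treats assessors as exchangeable random intercepts;
  systematic assessor-by-group confounding (an assessor seeing only CHR
  participants) is not modeled beyond what the random intercept absorbs.
* Role assignment from screen position is configuration, not inference; a
  recording with swapped tiles will silently swap the sign of every delay
  unless the caller supplies the correct mapping.
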