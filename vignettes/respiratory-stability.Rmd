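---
title: "Quantifying respiratory stability: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying respiratory stability: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respstab)
```

## The problem

Respiratory-gated imaging bins acquisition data by breathing phase, so its
accuracy depends on how stable the patient's breathing is. respstab scores
that stability from a plain time–amplitude respiration trace (abdominal
surface position against time, as recorded by an optical marker tracker)
by transforming it into four mathematical constructs — the phase-space
diagram, the Fourier amplitude spectrum, a modified Poincaré section, and
the largest Lyapunov exponent — and condensing them into four indices:

* **SD_x, SD_v** — dispersion (population SDs) of the Poincaré crossing
  coordinates; SD_x is the primary measure of *amplitude* regularity.
* **A1** — height of the fundamental spectral peak; a taller peak means a
  more stable breathing *period*, so the comparison direction is inverted
  relative to the other indices.
* **MUD−MDD** — maximal upward minus maximal downward drift of the
  end-of-exhale baseline; measures baseline instability.

Crossing amplitude regularity with period regularity yields the four-group
taxonomy: A (both regular), B (irregular period), C (irregular amplitude),
D (both irregular), each with or without baseline drift. The default
cutoffs (0.11 for SD_x, 0.062 for SD_v, 0.117 for A1, 0.349 for MUD−MDD,
in trace units) are published ROC-derived values; `roc_cutoff()` re-derives
cutoffs for locally recorded cohorts.

## The synthetic generator

No patient recordings ship with the package; every downstream stage is
validated against a generator with known ground truth. A trace is a
concatenation of raised-cosine cycles

$$z_i(t) = e_i + A_i\,\bigl(1 - \cos^{2n}(\pi t/T_i)\bigr), \qquad t \in [0, T_i),$$

anchored at the end-of-exhale level $e_i$ so consecutive cycles join
continuously at their shared trough. The $\cos^{2n}$ profile (default
$n = 2$) gives the flattened end-of-exhale plateau of real breathing.
Per-cycle amplitudes $A_i \sim N(\mu_A, \sigma_A)$ (truncated below at
$0.1\,\mu_A$) and periods $T_i \sim N(\mu_T, \sigma_T)$ (truncated at
$0.2\,\mu_T$) model breath-to-breath jitter; $e_i$ follows a reflected
random walk confined to $[0, \text{drift\_span}]$, updated once per cycle
so MUD−MDD stays interpretable as end-of-exhale drift; white noise with SD
`noise_sd` models the tracker.

Defaults were fixed once, as typical free-breathing values: $\mu_A = 1$ cm,
$\mu_T = 4$ s (0.25 Hz), `noise_sd` = 0.005 cm (sub-millimetre optical
tracking), 20 min at 25 Hz. The walk step SD is `drift_span/20`, chosen by
simulating the reflected walk alone so that a 20-min recording typically
realizes two-thirds to three-quarters of the allowed excursion. Group
presets use 2% relative jitter for "regular" axes, 25% period jitter and
30% amplitude jitter for "irregular" ones; these are calibration constants
of the package, not measured cohort values.

An earlier formulation pinned both cycle ends at $b_i - A_i$ with the walk
on $b_i$; per-cycle amplitude draws then create jump discontinuities at
cycle joints, which contaminate the velocity estimate with $|\Delta A| \cdot
f_s/2$ spikes and break the identity "segmented cycle amplitude = drawn
$A_i$". Anchoring at the trough removes both artifacts and matches the
field's convention that the breathing baseline is the end-of-exhale level.

What the generator does *not* emulate: cardiac-motion superposition,
inhale/exhale hysteresis, breathing-type switching (chest vs. abdominal),
and — important for one index — breath-to-breath *period* variation that
leaves the inhale velocity unchanged. In the generator a long cycle is a
uniformly stretched cycle, so velocity scales with $A_i/T_i$ and SD_v
responds to period jitter as well as amplitude jitter; in patients the
pause length varies more than the inhale speed. Passing tests therefore
show correctness of the estimators on this model, not that SD_v will
separate patient groups the same way.

## Cycle segmentation and screening

End-of-exhale troughs are found by prominence-filtered local-extremum
detection: candidate minima must have topographic prominence of at least
20% of the global peak-to-peak range and be at least 1.0 s apart (both
configurable). Neither rule is in the source method, which does not state
a peak-detection procedure; the values suppress sensor ripples and cardiac
oscillation at physiological breathing rates (0.1–0.5 Hz). Cycles run
trough to trough; the amplitude is the within-cycle maximum minus the
leading trough.

Cycles uncorrelated with the majority pattern are discarded before the
indices are computed: each cycle is length-normalized to 101 points and
Pearson-correlated against the point-wise *median* cycle (robust to the
outliers being screened); cycles with $r < 0.6$ are dropped worst-first.
The discard budget is a cap — at most 5% of cycles, with a minimum of one
when any cycle fails — because rejection is meant to remove occasional
artifacts, not to beautify a globally irregular recording; exceeding the
cap raises a warning instead of silently losing data.

## The modified Poincaré section

The section plane sits at the median point between the maximal and minimal
respiration points, and the recorded crossing is the first *sample* on the
inhale side of the plane rather than an interpolated intersection, so both
coordinates genuinely vary from cycle to cycle. Two design decisions here
are the most consequential in the package:

1. **Plane placement is per cycle** (`plane = "cycle"`, the default): each
   cycle is sectioned at its own midrange. A plane fixed at the *global*
   midrange (`plane = "global"`, offered for comparison) pins the crossing
   displacement to the plane level by continuity, so SD_x degenerates to
   the sampling granularity, bounded by $\max|v|/f_s$ plus noise — about
   0.02 cm for a 1-cm trace at 25 Hz — and can never reach the published
   0.11 cutoff, let alone the 0.07–0.25 range reported for patient groups.
   With per-cycle placement the crossing displacement tracks each cycle's
   mid-level, so SD_x responds to amplitude jitter (≈ σ_A/2) and to
   baseline drift, reproducing the scale on which the published cutoff
   operates.
2. **Direction conventions mirror under time reversal**: upward crossings
   record the first at-or-above sample, downward crossings the last
   at-or-above sample, so reversing a trace maps one onto the other
   exactly (asserted to 1e-9 in the tests).

One point is recorded per cycle and direction (the first crossing,
exhale-to-inhale by default). Discarded cycles are never sectioned. SDs
are population (ddof = 0) SDs.

## Spectrum and the period-regularity rule

The spectrum is a one-sided FFT amplitude spectrum with rectangular window
and `2/N` scaling, so a unit sinusoid over integer cycles yields a bin of
height exactly 1. The default detrend is linear, so slow baseline drift
does not leak into the breathing band (drift is measured separately by
MUD−MDD); note that linear detrending of a *finite* pure tone removes a
small non-zero fitted slope, so the textbook single-bin identities hold
under `detrend = "mean"`, which the analytic tests use. The fundamental
peak is the tallest local maximum in the physiological band (0.05–1.0 Hz
by default).

The visual rule for a regular period — one dominant fundamental peak, at
least twice the average height of other peaks, in a bell-shaped spectrum
centred on it — is operationalized as: `peak_ratio` = A1 over the mean of
other in-band local maxima (excluding the fundamental's main lobe, ±2
resolution bins, and maxima below 0.1% of A1, which are numerical floor),
and `concentration` = the fraction of in-band spectral energy within
±0.05 Hz of f0. The verdict requires `peak_ratio >= 2` (the stated
twofold rule) and `concentration >= 0.8`. The concentration threshold is
a package calibration: on 20-seed preset cohorts the concentration of
regular-period traces is 0.93–0.94 and of period-jittered traces
0.54–0.69, so 0.8 separates them cleanly, whereas a 0.5 threshold would
pass nearly everything.

Two caveats are inherited from the source method and documented rather
than solved. First, A1 is normalization-dependent: under a different
spectral convention, amplitude unit, or recording duration the 0.117
cutoff does not transfer (shorter records have coarser bins that collect
more of a smeared line, raising A1; the cutoffs presume 20-min records).
Second, group *means* need not classify into their group: the published
group-D mean A1 of 0.122 lies above the 0.117 cutoff, so that index
vector classifies as period-regular; this is a property of means versus
ROC cutoffs, not a defect of the rule.

## Largest Lyapunov exponent

The exponent is estimated by the divergence-curve method: delay-embed the
displacement (delay = first 1/e crossing of the autocorrelation; dimension
= smallest passing a false-nearest-neighbour screen, never below 2), find
each embedded point's exact nearest neighbour outside a Theiler window of
one mean breathing period, follow the pairs forward, and fit a straight
line to the mean log-distance over the first mean period of expansion
steps — the pre-fold-back scaling region of quasi-periodic signals. The
slope, in 1/s, is the exponent: 0 for purely regular breathing, positive
for diverging (chaotic) dynamics, negative for trajectories converging to
a stable pattern.

Numerical choices: the pair average keeps a *constant cohort* — only pairs
that can be followed for the whole expansion range enter. Per-step dropout
of pairs that run off the end censors the most-evolved pairs first, and on
contracting signals the composition shift cancels the contraction (an
oscillation damped at rate λ came out at −λ/100 under per-step dropout and
at exactly −λ with the fixed cohort). Exactly repeating segments (zero
distance) carry no divergence information and are skipped; the neighbour
search is exact brute force in compiled code (quadratic, a few seconds at
30 000 samples on one CPU). The false-nearest-neighbour screen runs on an
evenly strided subset of at most 1500 embedded points.

The published per-patient exponents (−3.76 to −0.43, units unstated) are
not reproducible: they depend on an unknown normalization, embedding and
fit range. What the package can and does verify is the limit and sign
semantics: a noiseless periodic 20-min trace gives |LLE| < 0.05 s⁻¹, the
Lorenz system gives a positive exponent, and a damped (regularizing)
oscillation gives a negative exponent that grows more negative with
faster regularization. A spliced trace (noisy first half, clean second
half) does *not* produce a negative exponent under any divergence-curve
estimator — pairs start at their minimal distance and phase offsets
persist — so convergence is demonstrated with genuinely contracting
signals instead.

## Classification and cohort statistics

`classify_trace()` applies the inclusive-toward-regular rule: amplitude
regular iff SD_x ≤ cutoff (optionally also SD_v under
`amp_rule = "both"`; SD_x alone is the default because it is the strongest
published discriminator), period regular iff A1 ≥ cutoff, drift present
iff MUD−MDD > cutoff; boundary values side with regular. ROC cutoffs are
derived by the Mann–Whitney identity (ties half-counted) with the Youden
point reported at the midpoint between adjacent distinct scores and
automatic orientation flipping. Group differences use classical one-way
ANOVA with Scheffé's all-pairs criterion at α = 0.05, reported both as a
pairwise table and as the compact ordered-subset string ("A, B < C, D").

## Problem sizes and runtime

The validation suite uses 20-min traces (30 000 samples) where the claim
concerns the published operating point — the regular-respiration exponent
limit and the 50-traces-per-group recovery experiment (at least 90% of the
traces must be assigned their generating group with the default cutoffs) — and 5-min traces for distributional and invariance checks,
where duration only adds resolution. The ANOVA type-I calibration uses
200 simulated null cohorts of 4 × 8 observations.

## Known limitations

* All cutoffs are in trace units and presume the recording conventions
  above; cohorts recorded differently should re-derive them with
  `roc_cutoff()` on a locally graded sample.
* SD_v is reported but not used in the default rule; in the generator it
  conflates period and amplitude jitter (see above).
* MUD−MDD measures the *range* of end-of-exhale positions, so heavy
  amplitude irregularity with trough-level excursions can register as
  drift; the drift flag is most meaningful for traces whose amplitude is
  regular.
* The visual grading that defined the original reference standard cannot
  be reproduced; synthetic presets stand in for it, with the calibration
  constants documented here.
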