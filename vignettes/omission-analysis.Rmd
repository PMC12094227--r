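---
title: "Analysing spiking responses to omitted visual stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spiking responses to omitted visual stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omispike)
```

## The problem

In visual change-detection experiments, mice view a continuous train of
natural images (eight identities, 250 ms each) in which a presentation is
occasionally omitted. What happens in the brain at the moment a predictable
stimulus fails to arrive is a long-standing question: genuine "omission
responses" should be time-locked to the expected onset, whereas apparent
omission modulation can instead arise from firing-rate dynamics that were
already in motion — decaying stimulus responses and inter-stimulus ramping.
`omispike` implements, end to end, the spiking-level analyses used to
separate these possibilities: omission-modulation scoring, ramp-versus-step
model comparison, functional clustering of visual-cortex units, population
coupling, monosynaptic inference from fine-timescale cross-correlograms,
cross-area interaction modelling, and image-identity decoding. A synthetic
session generator with known ground truth makes every stage testable without
any data download.

## The synthetic session generator

The generator reproduces the statistical structure the analyses assume.

**Stimulus schedule.** Presentations recur with a fixed cycle; each trial
shows one of eight images for a truncated-geometric number of repeats
(support 5–11; success parameter `geom_p = 0.3` — the distribution family
and support are given, the parameter is our choice and is configurable).
Interior presentations are omitted independently with probability 0.05.
Two slots are never given an omission draw: the first and last of a trial,
and the slot immediately after a realized omission. This guarantees exactly
that every omitted slot sits between two presented repetitions of the same
image, and makes the omission probability among *eligible* slots exactly
the nominal 5%. The 250-ms image duration is fixed by the task; the
gray interval between images is not printed anywhere we could anchor it, so
the default cycle is 0.75 s (250 ms image + 500 ms gray), configurable via
`cycle_period_s`.

**Units.** Spike trains are inhomogeneous-Poisson realisations (sampled by
thinning at the unit's rate ceiling) of archetype rate templates composed
with the schedule:

* `transient_on` — sharp onset transient (40 ms decay) during the image;
* `sustained_on` — elevated plateau for the full presentation, followed by
  an exponential persistence tail into the gray (time constant 250 ms,
  amplitude 0.8 of the plateau). The tail matters: it is the mechanism by
  which ON units appear *down-modulated* when an omission window is
  compared to the immediately preceding gray — modulation without any
  omission-locked process;
* `ramp_to_offset` — rate grows through the image, peaks at offset, decays
  through the following interval;
* `step_off_on` — suppressed by the image (to 20% of baseline), elevated at
  a fixed level between images and throughout an omitted cycle;
* `ramp_off` — suppressed by the image, then ramping linearly through the
  inter-stimulus interval toward the next expected onset, and continuing
  *without interruption* through an omission (capped at 2.5 amplitudes);
* `hippocampal_step` — no image response at all, but a rate step at the
  expected onset of an omitted image, held until the post-omission image;
* `unmodulated` — homogeneous Poisson control.

STIM-ON archetypes (the first three) receive per-image multiplicative
log-normal tuning gains (`tuning_gain_sd = 0.3` by default; selectivity is
known to exist, its magnitude is our choice); STIM-OFF archetypes are
image-agnostic by construction. STIM-OFF baselines are set higher than
STIM-ON ones, mirroring their higher stimulus-free firing rates. Default
baselines (3–6 Hz) and amplitudes (6–12 Hz) are ordinary cortical values.

**Behaviour.** Running speed is a smooth noise process around 40 cm/s with
an omission-triggered dip whose onset lags the omitted onset by 0.5 s and
which bottoms out ~0.3 s later — i.e. after the post-omission image has
already appeared. Pupil diameter receives a slight further constriction
after omissions and is median-normalised per session (traces at 60 Hz).

What the generator does **not** emulate: correlated trial-to-trial
variability within an area (units are conditionally independent given the
schedule), oscillations and population bursts, adaptation across repeats,
representational drift, and any continuous field signal. Tests passing on
this generator therefore validate the *machinery* — estimators, selection
rules, calibration — under the designed conditions, not every property of
real recordings.

## Scoring omission modulation

PSTHs count spikes into 10-ms bins around events and divide by bin width and
event count. The z-scored PSTH is normalised against its own mean and SD
over the full displayed window; no reference segment is named by the
analyses we reproduce, and self-normalisation keeps units with different
dynamic ranges comparable. `delta_z` is the mean z-rate over the omission
window (0–250 ms); significance comes from a two-sample Wilcoxon rank-sum
test of per-event rates in that window against the immediately preceding
250-ms baseline, with per-event rate = count / window length and counts
entering as-is (ties included). The ramping index is
`RI = log2(R_late − R_early)` with the early/late means taken over the first
and last 100 ms of the omitted-stimulus window. The formula is not
scale-invariant, so the scale matters: we compute it on z-scored rates
(matching how the responses are displayed), and the raw-Hz alternative is a
one-argument change. A non-positive difference leaves the log undefined;
we return `NaN` with a flag rather than clipping.

Stimulus-specificity of omission responses is tested on units "tuned to one
image", operationalised as a one-vs-rest rank-sum win for exactly one image
at Bonferroni-corrected alpha over the eight images (no criterion is printed
anywhere; this is the simplest defensible one). The test then compares
omission-window rates between omissions of the preferred versus
non-preferred image.

## Ramp versus step: linear and sigmoidal population fits

Per session, the population response is the mean z-PSTH of significantly
up-modulated units over ±250 ms around omission onset. Both a line and the
four-parameter sigmoid

$$y = \Delta + \frac{A}{1 + e^{-\sigma (x - c)}}$$

are fitted by least squares; the sigmoid by multi-start Levenberg–Marquardt
(σ initialised on {5, 50, 500} s⁻¹, c on the window quartiles, Δ and A from
the data range; σ constrained positive, ties across restarts broken toward
the shallower slope — a decreasing population would be fitted on its negated
trace). Fit quality is the mean held-out R² over eight *contiguous-block*
folds: random folds would leak the smooth trend into every fold. Held-out R²
is computed against the training-fold mean (a predictive Q²): test blocks of
a trending signal have almost no internal variance, so centring on the test
mean would be degenerate. Per-fold sigmoid fits warm-start from the
full-data optimum.

An area is called *sigmoidal* when a one-sided rank-sum test (sigmoid >
linear, matching the directional claim being tested) on per-session R²
values gives P < 0.05 **and** the median sigmoid R² exceeds the linear one.
Pooled fitted slopes are classified into modes by a kernel density estimate
on log₁₀σ (Silverman's bandwidth; the three modes near 10, 60 and 300 s⁻¹
are only resolvable on a log axis), with troughs between the up-to-three
dominant peaks as boundaries and each area labelled by the mode containing
its median σ.

## Functional clustering

Each unit's feature vector is its z-PSTH spanning the preceding stimulus,
the omission and the following stimulus (−0.75 to +1.5 s at the default
cadence, 10-ms bins); k-means operates on the rows of the unit-by-unit
Pearson correlation matrix. The number of clusters combines two criteria
computed over k = 1…10:

* **Elbow** — the point where the slope of the dispersion profile changes
  most drastically, operationalised on log W_k as a *ratio* of successive
  drops (slope into k over slope out of k). The absolute second difference
  always peaks at k = 2 (the first split removes the most variance by
  construction), so a relative detector is required for "most drastic" to
  mean anything. Functional populations are hierarchical — the ON/OFF split
  and the archetype level both flatten the curve — so the elbow is taken at
  the *last* drastic flattening (ratio ≥ 2) whose incoming drop is a
  material share (≥ 5%) of the total decline: the onset of the plateau, not
  jitter within it.
* **Gap** — `Gap(k) = E*{log W_k} − log W_k`, with the reference expectation
  from 50 Monte-Carlo draws of a uniform distribution over the
  *principal-component-aligned* bounding box of the data. We first
  implemented the plain feature-range box and found the gap strictly
  monotone in k on correlation-matrix rows (their features are strongly
  correlated, so the axis-aligned box vastly overestimates the null
  dispersion at every k); the rotated box is the standard remedy and makes
  the gap peak at the planted k. The reported k uses the standard-error
  rule — the smallest k with `Gap(k) ≥ Gap(k+1) − 2·SE(k+1)` — with a
  factor of 2 on the Monte-Carlo SE because at a few hundred units the gap
  creeps upward past the true k by slightly more than one bare SE (the same
  reason reference implementations expose an SE factor). The plain argmax
  is available by option.

The session optimum is the mean of the two criteria rounded half-up, and the
final model uses the mode across sessions. Fitted clusters receive semantic
labels by one-to-one matching (exhaustive over permutations for k ≤ 7) of
their mean z-PSTHs to the noise-free archetype templates, and a STIM-ON /
STIM-OFF class. A robustness variant re-clusters with the omitted cycle's
bins removed from the features (`exclude = c(0, 0.75)`).

Elapsed time within the omission is decoded per cluster by 10-fold
cross-validated linear regression from z-scored 50-ms counts to the bin
index, summarised as the per-fold mean absolute error.

## Coupling, connectivity, cross-area interaction, decoding

**Population coupling** follows the leave-one-out construction: the summed
rate of the remaining units is binned at 10 ms, mean-centred and smoothed
with a Gaussian kernel; the coupling index is the Pearson correlation with
the unit's own binned rate. The printed kernel width "12/2 ms" is ambiguous;
we read it as a 6-ms half-width and use a 6-ms-SD Gaussian, exposed as a
parameter. The stPR is the spike-triggered average of the smoothed
population rate over ±0.4 s. Behaviour scores are absolute Pearson
correlations between binned rates and the behaviour variable interpolated
linearly onto bin centres. Cluster-versus-target cross-correlograms use
multi-unit activity subsampled to equal spike counts across clusters,
min-max scaled, with the ±20-ms area under the curve as the statistic.

**Monosynaptic inference** builds 0.4-ms-bin cross-correlograms over ±50 ms
(a compiled kernel counts the pairs) and compares them with interval-jitter
surrogates of the postsynaptic train. The jitter interval is 5 ms — long
enough to destroy monosynaptic-timescale structure, short enough to preserve
slow comodulation; the method's source names no interval, threshold or lag
window, so these are package defaults: excitatory peaks are sought at
+0.8–2.8 ms, inhibitory troughs at +0.8–4 ms. Significance uses the
maximum- (minimum-) statistic over the lag-window bins across surrogates — a
global correction, because pointwise bands alone inflate false positives —
and the overall alpha is split evenly between the excitatory and inhibitory
tests so the per-pair family error stays at alpha. Edge strength is the
excess (deficit) of coincidences per presynaptic spike at the peak lag.
Note the permutation p-value floor is `1/(n_surrogates + 1)`: detecting at
alpha = 0.05 split two ways requires at least ~100 surrogates (the default
is 200).

**Cross-area interaction.** Spike counts in 50-ms bins within the
presentation/omission window are residualised against the condition PSTH and
z-scored per unit; the ridge model `B = (XᵀX + λI)⁻¹XᵀY` predicts one area's
residuals from the other's. Trial counts are matched across conditions by
seeded subsampling of the larger set. λ is selected on each training fold by
inner cross-validation over a 10-point logarithmic grid (10⁻²–10³), and
performance is pooled held-out `R² = 1 − SSE/SST` over target units. The
interaction strength is `R²(stimulus) − R²(omission)`; positive means better
prediction during stimuli. Canonical correlations are computed by whitening
each side and taking singular values of the whitened cross-covariance, with
a small diagonal loading when trials are scarce relative to the joint unit
count; permutation nulls provide the reference baseline.

**Image-identity decoding** trains, per 50-ms bin around the omission, a
linear multiclass SVM (one-vs-one maximum-margin classifiers with majority
voting, cost fixed at 1) on min-max-normalised per-unit counts, with
stratified 10-fold cross-validation. Normalisation is fitted on training
folds only and test features are clipped to [−0.5, 1.5]. Labels are the
image flanking the omission; chance is 1/8. One practical caveat the
synthetic work surfaced: with few omissions the empirical class priors are
uneven and a margin classifier drifts toward majority classes, so chance
calibration should be read against a permutation distribution at a realistic
number of omissions (≈200+), which is what the calibration tests do.

## Numerical choices and degenerate inputs

Zero-variance PSTHs yield an all-zero z-rate with a flag; zero-variance
units are dropped (with a warning) from response matrices and
residualisation. Quality filters are strict inequalities, so boundary units
are excluded; a 0.4-ms waveform falls into neither cell-type rule and stays
unclassified. Fewer than two omissions, empty spike trains, silent units,
constant behaviour traces, and identical R² distributions all return flagged
results rather than errors. All generators and stochastic stages are pure
functions of (configuration, seed); `run_pipeline()` fans a single seed into
per-stage seeds with a counter scheme and stamps every output with the
configuration hash.

## Problem sizes used by the test-suite

The packaged tests exercise the pipeline at desk scale: sessions of
150–1100 trials (≈50–230 omissions), 10–120 units, 100 sigmoid-recovery
replicates, 100 area-classification meta-replicates of 20 step and 20 ramp
sessions each, 50 cluster-number seeds, 30 planted synapses with 1000
null pairs, and 100 + 100 planted-latent sessions for the interaction sign.
These sizes were chosen so each suite completes in minutes while leaving
the statistical margins (binomial confidence intervals at the stated rates)
meaningful.

## Known limitations

Semantic cluster labels assume the fitted clusters resemble the archetype
templates; on real data with novel response types the nearest-template
label is only a name, not an identity. The monosynaptic detector's defaults
(jitter interval, lag windows) are tuned for cortical latencies at
moderate rates and should be revisited for very high-rate or bursty units.
The ridge interaction measure is symmetric in its conditions but not a
directed or causal claim. The CCA loading constant is a numerical
stabiliser, not an optimised regulariser.
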