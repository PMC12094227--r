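# omispike

Spiking-level analysis of stimulus-omission responses in regular visual
stimulus trains.

In change-detection experiments, mice watch a continuous sequence of natural
images (eight identities, 250 ms each) in which a presentation is
occasionally omitted (5% of eligible slots, always between two repeats of
the same image). Whether neurons *respond* to the missing stimulus — a
time-locked change at the expected onset — or merely continue dynamics set
in motion by the preceding images is the scientific question this package's
tooling addresses. It is aimed at systems neuroscientists analysing
event-aligned spike trains from such paradigms, and at methodologists who
want a fully synthetic, ground-truthed test bed for the analysis chain.

## What it implements

* **Synthetic sessions** — stimulus schedules (truncated-geometric trial
  lengths, stochastic omissions with identical flankers),
  inhomogeneous-Poisson units realising seven response archetypes
  (transient/sustained/ramp-to-offset STIM-ON; step-OFF/ON and
  ramp-to-onset STIM-OFF; a hippocampal step responder that holds its rate
  from the expected onset to the next image; an unmodulated control), and
  running/pupil traces with a lagged post-omission slowdown.
* **Omission scoring** — 10-ms PSTHs, omission-window z-scores Δz, Wilcoxon
  rank-sum significance against the preceding baseline window, ramping index
  `RI = log2(R_late − R_early)`, and a stimulus-specificity test for units
  tuned to a single image.
* **Ramp vs step** — per-session population fits of a line and of
  `y = Δ + A / (1 + exp(−σ(x − c)))` with 8-fold contiguous-block
  cross-validation; areas labelled *sigmoidal* by a one-sided rank-sum test
  on R² distributions; slope-mode classification from the multimodal
  distribution of fitted σ.
* **Functional clustering** — k-means on the unit-by-unit correlation matrix
  of omission-aligned responses, with the number of clusters chosen by an
  elbow criterion on the dispersion profile and the gap statistic
  `Gap(k) = E*{log W_k} − log W_k`; semantic archetype labels; composition
  tables; elapsed-time decoding per cluster.
* **Coupling & connectivity** — Okun-style leave-one-out population
  coupling and stPR; speed/pupil scores; spike-matched cluster-vs-target
  cross-correlograms; and putative monosynaptic connections from 0.4-ms
  cross-correlograms tested against interval-jitter surrogates with a
  max-statistic correction.
* **Cross-area interaction** — ridge prediction
  `B = (XᵀX + λI)⁻¹XᵀY` between areas' residual activity, with the
  interaction strength `R²(stimulus) − R²(omission)`, plus canonical
  correlations.
* **Decoding** — per-50-ms-bin linear multiclass SVM decoding of image
  identity around the omission (chance 1/8).

## Worked example

```r
library(omispike)

sched <- generate_schedule(n_trials = 300, seed = 42)   # ~2000 slots, ~100 omissions
units <- filter_units(generate_units(sched, seed = 43))
mod   <- omission_modulation(units, sched)
dplyr::count(mod, sign_class)
#>   sign_class     n
#> 1 down          13
#> 2 ns            76
#> 3 up            41
```

41 of 130 units are significantly up-modulated during omissions and 13 are
down-modulated — on synthetic ground truth these are the hippocampal step
and inter-stimulus ramp units (up) and the stimulus-driven units whose
persistence tails decay through the gray period (down).

```r
hpc  <- units[units$area == "CA1", ]
resp <- population_response(hpc, sched, mod[mod$unit_id %in% hpc$unit_id, ])
fit_sigmoid(resp)
#> <omi_fit> sigmoid fit
#>   Delta=-0.687 A=1.376 sigma=3733.7 1/s c=-0.000 s
#>   cross-validated R2 = 0.912
fit_linear(resp)$R2_cv
#> [1] 0.654
```

The hippocampal population steps at the expected stimulus onset: the
sigmoid centres at c ≈ 0 with a very steep slope and clearly beats the
line out of sample (0.91 vs 0.65). A ramping visual population would give
the two models near-identical R².

```r
vis <- units[units$area == "VISp", ]
rmx <- build_response_matrix(vis, sched)
cl  <- cluster_units(rmx, k = 5, seed = 45)
dplyr::count(tidy(cl), semantic_label, class)
#>   semantic_label class        n
#> 1 ramp_off       STIM_OFF    20
#> 2 ramp_to_offset STIM_ON     20
#> 3 step_off_on    STIM_OFF    20
#> 4 sustained_on   STIM_ON     20
#> 5 transient_on   STIM_ON     20
```

All 100 visual-cortex units are returned to their generating archetype.
`run_pipeline(pipeline_config(seed = 1))` chains every stage —
synthesis, QC, scoring, fitting, clustering, coupling, connectivity,
cross-area interaction, decoding — and returns the per-stage tables plus a
machine-readable summary stamped with the configuration hash.

See the vignette (`vignettes/omission-analysis.Rmd`) for the model
assumptions, parameter defaults and numerical choices.

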