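---
title: "Methods: sensorized motor-cognitive dual-task analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensorized motor-cognitive dual-task analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdtkit)
```

## The problem and the model

Motor-cognitive interference — the degradation of a movement when a
concurrent cognitive task competes for shared neural resources — is a
candidate digital biomarker for early cognitive decline. `mcdtkit`
implements a full analysis chain for sensorized motor-and-cognitive
dual-task (MCDT) protocols: five motor exercises (forefinger tapping FTAP,
thumb-forefinger tapping THFF, toe tapping TTHP, heel tapping HTTP, and a
10-m walk GAIT), each performed alone (CL0) and while counting backwards
by 1, 3 or 7 (CL1–CL3), recorded by a wrist/finger- or foot-mounted IMU at
100 Hz.

The chain is: low-pass filtering and cycle segmentation of the angular
velocity; extraction of 45 kinematic parameters per load level (8 per
tapping task, 13 for gait; 180 feature columns over the four loads);
dual-task costs; per-exercise pooled indices; and leave-one-out
cross-validated logistic classification of three diagnostic groups —
cognitively healthy older adults (OA), subjective cognitive impairment
(SCI) and mild cognitive impairment (MCI).

The package's central quantity is the *weighted* dual-task cost. The
standard cost of feature $f_i$ for exercise $Ex$, load $CL_k$ and subject
$s_j$ is

$$DTC_i(Ex, CL_k, s_j) = 100\,\frac{f_i(Ex, CL_k, s_j) - f_i(Ex, CL_0,
s_j)}{f_i(Ex, CL_0, s_j)},$$

which ignores whether the participant actually performed the cognitive
task. A participant who silently stops counting shows unchanged motor
output and a deceptive cost near 0%. The weighted variant multiplies the
dual-task feature by a cognitive weight $Z_c \in [0.01, 1]$ before the
cost is taken: the number of correct counting responses $N_c$ is z-scored
across the analyzed sample within each (exercise, load) and affinely
rescaled into $[0.01, 1]$ (the lower bound avoids exact-zero weights).
Because z-scoring and min-max rescaling are both affine, the composition
equals a direct min-max rescale of the raw counts — a property the test
suite asserts to $10^{-12}$. With all weights at 1 the weighted cost
reduces exactly to the standard cost; in the stop-counting limit case
($f_k = f_0$, $Z_c = 0.5$) the weighted cost is $-50\%$ where the
standard cost is 0%.

## Signal processing choices

* **Filtering.** Fourth-order low-pass Butterworth, cutoff 5 Hz for
  tapping and 3 Hz for gait. The pass is applied forward and backward so
  that event times are not lag-shifted; this zero-phase choice is a
  package decision made because downstream features are event-timed. The
  implementation pads with odd reflections and starts each pass in its DC
  steady state, so a constant input is reproduced exactly at the edges.
* **Tap segmentation.** Cycles are detected on the filtered angular
  velocity as an opening peak (positive local maximum) paired with the
  first closing trough that follows it. Band-limiting a ~2 Hz biphasic
  pulse train to 5 Hz creates rebound oscillations between taps of
  roughly 15–20% of the lobe amplitude, so extrema must exceed
  `peak_frac` (default 0.35) of the trial's 98th-percentile amplitude, in
  addition to a fixed 10°/s floor and 5× the still-phase noise SD. The
  opening→closing transition (the cycle's `t_peak`) is the zero crossing
  between the lobes, refined on the *unfiltered* signal within ±30 ms of
  the filtered-domain candidate: the refinement recovers noiseless event
  times to sub-sample accuracy despite the smoothing.
* **Gait segmentation.** Standard shank/foot gyroscope logic: mid-swing
  is a prominent positive peak of the sagittal angular velocity; toe-off
  is the last negative minimum before it and heel strike the first after
  it; movement onset and foot-flat are where the unfiltered signal leaves
  and durably (≥50 ms) re-enters a quiet band. Extrema are refined on the
  raw signal as above. Partial cycles at window boundaries are discarded.
* **Integration.** Angular excursions use the trapezoidal rule at the
  native 10 ms sample spacing. For full cycles a linear detrend forces
  the integrated angle at cycle end back to its start (zero-velocity
  update), which removes a constant gyroscope bias exactly. Excursions
  and peak velocities are computed on the unfiltered channel within the
  detected windows: integration itself averages the noise, and computing
  them on the filtered trace would attenuate brief lobes near the band
  edge.
* **Velocities.** Opening/closing velocity is the per-cycle *peak*
  angular speed in the respective phase (the conventional tapping
  metric), averaged across cycles, with SDs across cycles as the
  variability features.
* **Energy proxy.** IAV integrates the Euclidean norm of the
  acceleration after subtracting the still-phase mean vector; without
  that baseline removal gravity would dominate the integral.

## Pooled indices

Each exercise's candidate pool contains its weighted-cost columns across
all three dual-task loads (24 columns for a tapping task, 39 for gait).
Pooling across loads is a package decision — it maximizes the information
available to the screen and can be switched to per-load pools. Screening
deletes, iteratively, the column with the most Spearman $|\rho| \ge 0.4$
partners; ties fall to the smaller absolute Cohen's *d* on the MCI-vs-OA
contrast (the primary diagnostic contrast), then to a configurable
priority list. At most 6 mutually low-correlation components survive;
each is oriented so that higher means better functioning (counts,
excursions and velocities positive; variability, time and energy features
negative — the mapping is explicit and overridable, never defaulted
silently), min-max normalized to $[0,1]$, and averaged per participant
with a missing-aware mean. $|\rho|$ is used because anti-correlated
columns are equally redundant. The deletion trace is emitted with the
selection so the step is auditable.

## Classification

Models use the pooled index of one exercise plus age and the Frontal
Assessment Battery score. The binary problem (MCI vs OA) is a binomial
logit and the ternary problem a single multinomial logit, both fit by
`nnet::multinom` on internally standardized predictors with a small
weight decay (default $10^{-6}$) that keeps coefficients finite under the
quasi-separation that is likely in leave-one-out folds of a 44-person
cohort. Validation is leave-one-out: n refits, each predicting only its
held-out participant, with standardization recomputed inside every fold.
Probability ties resolve deterministically to the first class in the
fixed (OA, SCI, MCI) order. Metrics are sensitivity/specificity/accuracy
for the binary problem and per-class plus support-weighted
recall/precision/F1 and overall accuracy for the ternary one; weighted
recall equals overall accuracy by construction, which the tests assert on
random confusion matrices. Reports round to integer percent; raw values
are retained.

## The synthetic cohort

No clinical recordings ship with the package; a seeded generator
produces a cohort with the statistical structure the analysis assumes,
so every stage is testable end to end.

* **Demographics.** 10 OA / 17 SCI / 17 MCI; ages drawn from
  group-specific normals centred on medians 63 / 72 / 73 years; FAB
  centred 17 / 15.5 / 13.5 (ordered OA > SCI > MCI); MMSE truncated at
  the 24-point exclusion bound; sex and education drawn from group
  proportions.
* **Tapping signals.** 3 s still then 15 s of biphasic raised-cosine
  pulses on gyro-y: a positive opening lobe and negative closing lobe
  whose integrals equal the per-tap excursion, with log-normal jitter on
  period and amplitude, Gaussian noise (SD 2°/s) and a slow linear bias
  drift (0.2 °/s per s). Base rate/excursion (e.g. 2.0 Hz / 40° for OA
  finger tapping, scaled down for foot tasks) fall and the cycle
  coefficient of variation rises with load, more strongly for MCI than
  SCI than OA — the assumed interference ordering, validated by the
  config constructor.
* **Gait signals.** Per-stride templates — negative toe-off lobe,
  positive mid-swing lobe, negative heel-strike lobe, near-zero stance —
  covering 10 m at a group-dependent stride length/time (e.g. 1.30 m /
  1.15 s for OA down to 1.10 m / 1.40 s for MCI), stance fraction 0.60.
  The three lobes integrate to zero, so the zero-velocity update is
  consistent with the template; its drift-corrected peak swing angle
  (half the configured swing excursion) is recorded as ground truth.
* **Counting responses.** Censored Poisson counts whose rates fall with
  load and group (e.g. OA 14 → 5.5 expected correct responses from CL1 to
  CL3; MCI 11 → 2.5). The study reports no per-group response
  distributions, so these rates are package defaults chosen to span the
  plausible range of serial-subtraction output in 15 s; they are config
  fields, not calibrated constants.

Determinism: every draw derives its own 31-bit seed from the base seed
and the (participant, exercise, load) identity, so any single trial is
reproducible in isolation and identical configurations reproduce
identical studies byte for byte.

What the generator does *not* emulate: sensor dropout, attitude drift
requiring orientation fusion, left/right asymmetry, amplitude-dependent
noise, or the correlation structure of real neuropsychological
batteries. Passing tests therefore demonstrate that the pipeline's
algebra and detectors behave as specified on signals with the assumed
structure — not that the classifier magnitudes would replicate on
clinical data, whose group differences may be weaker and differently
shaped than the configured ones.

## Numerical and degenerate-case decisions

* A stated "100 ms" integration subinterval contradicting the 100 Hz
  sampling is resolved in favour of the native 10 ms spacing.
* Zero or negative single-task baselines make the (scale-relative) cost
  undefined; cells go missing with a warning, never sign-flipped.
* Degenerate cognitive spreads (one participant, or all counts equal)
  give weight 1 — absent spread there is no evidence of differential
  commitment, and 1 reproduces the unweighted cost.
* All-equal inputs to the bounded rescale map to the upper bound.
* Fewer than two detected strides yields a missing gait record with a
  warning; tapping SD features are missing below two cycles.
* Kruskal–Wallis on all-identical values returns 0 with a warning (the
  tie correction degenerates). The package reports df = groups − 1.
* Pearson chi-square is uncorrected (no Yates continuity correction),
  which reproduces the cohort tables' printed statistics exactly.
* Quartiles are linear-interpolation (type 7).

## Problem sizes used by the tests

The default simulated study is the 44-participant, 5-exercise, 4-load
protocol (880 trials, ~20 s on one CPU). The heavier acceptance checks
run the tapping arm of 20 seeded cohorts for the MCI-vs-OA cross-validated
baseline comparison and a 300-observation null simulation for the
chance-level check; both finish in a few minutes.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(cohort = cohort_config(seed = 1))
res <- run_pipeline(cfg)
res$summary
```

## Known limitations

Detector constants (thresholds, refractory windows, refinement widths)
are reconstructed, not transcribed from any reference implementation, and
are exposed in `tap_detector_params()` / `gait_detector_params()`. The
per-exercise component lists chosen by the screening step depend on the
cohort at hand; the deletion trace exists precisely so that this step can
be audited. Classification magnitudes on synthetic cohorts reflect the
generator's configured effect sizes, not clinical reality.
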