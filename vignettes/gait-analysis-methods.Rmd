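---
title: "Methods: insole GRF gait analysis and its synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insole GRF gait analysis and its synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolegait)
```

# The measurement model

Pressure-sensitive insoles record a grid of plantar pressures per foot at
100 Hz. Summing all sensors of one insole per frame yields the vertical
component of the ground reaction force (GRF) for that foot
(`sum_sensors()`). During stance the vertical GRF of walking is M-shaped: a
heel-strike loading peak (HPF) near a quarter of stance, a mid-stance valley
(MSF) as the contralateral leg swings past, and a push-off peak (TOF) in late
stance; during swing the force is zero up to sensor noise. All of the
package's kinematic and kinetic parameters derive from the two per-foot GRF
series plus the subject's weight and the walked distance.

# Event detection

The pipeline smooths each series with a centered 5-sample moving average
(`moving_average()`), then finds contact phases as runs of force above a
threshold equal to 5% of the median per-stance peak (`detect_contacts()`).
A pure local-minima search is ill-posed here: during swing the force sits at
(or near) zero for dozens of samples, so "the" minimum between stances is a
plateau of ties, and the moving average additionally smears each contact
edge outward by half the window. Each run boundary is therefore refined by
back-extrapolating the supra-threshold edge to zero force — the standard
onset technique for force-platform data. Samples closer than two to the
threshold crossing are excluded from the fit (they carry the smoothing
spread), up to four clean edge samples below 60% of the stance peak are used,
and a quadratic is fit because the loading and unloading ramps are visibly
curved at this scale; the root nearest the crossing, clamped to ±3 samples,
becomes the event, reported at sample resolution (10 ms at 100 Hz, matching
the achievable precision). On noise-free synthetic gait this recovers every
contact within one sample; under 0.02 BW measurement noise, better than 99%
of events stay within two samples.

Turns at the walkway ends distort stride timing. Stride durations are
compared against a running median (window 9 strides); strides deviating by
more than 3 MAD are flagged invalid together with the stride immediately
following each (`remove_outlier_strides()`). The MAD is floored at 1.5
samples so that quantization jitter on very regular gait is never flagged.
Nothing is deleted — flags and reasons are kept, which also makes the filter
idempotent.

# Kinematic parameters (28)

Per foot and stride: stride time (strike to next strike), stance time
(strike to toe-off), swing time (stride − stance), and their
coefficients of variation (`CV = 100·sd/mean`, sample sd). PST/PSWT are
stance/swing as a percentage of stride. Double support time (DST) is the
total bilateral-contact time within a stride window; with both
double-support intervals per stride counted, symmetric gait with stance
fraction *c* and step fraction 1/2 gives `DST = 2·(c − 1/2)·stride`. DST is
only defined for windows containing exactly two bilateral-contact segments;
windows at recording edges or bordering removed turns are excluded rather
than contributing corrupt values to DST variability.

Gait asymmetry compares mean swing times:
`GA = 100·|ln(SSWT/LSWT)|`. Bilateral coordination uses the phase of the
contralateral strike within each reference stride,
`phi_i = 360·(t_Si − t_Li)/(t_L(i+1) − t_Li)`, with the leg of longer mean
swing as reference (ties go to the left leg). Windows run between
*consecutive* reference strikes and only contribute when the reference
stride is valid and contains exactly one contralateral strike — a window
must never span removed turn strides, which would produce spurious phases
far from 180°. The phase coordination index is `PCI = phi CV + phi
deviation`. The deviation is normalized to percent by default
(`100·mean|phi−180|/180`), making PCI a sum of two percentages; the
raw-degree variant is always emitted alongside (`phi_deviation_deg`) and the
convention is a config switch, since either unit is defensible.

Cadence is the dominant periodogram frequency of the mean-removed combined
(left + right) GRF in 0.5–4 Hz (`stats::spec.pgram`). The combined signal
fluctuates at the *step* rate, so the estimate is about `2/stride time`
(≈1.8 Hz for typical gait) even though conventionally labeled strides/s.
Speed and step length come from walked distance over duration and over step
count; every detected foot-strike counts as a step (turn strides are real
steps — they are excluded from timing statistics, not from the count).

# Kinetic parameters (24)

Cycles are segmented from the *raw* series between each valid strike and
toe-off — smoothing exists for event detection and would attenuate and
shift the peaks — normalized by body-weight force (`weight·9.81` N) and
linearly resampled to a 101-point 0–100% stance grid. Per cycle, HPF is the
maximum over the first half of stance, TOF the maximum over the second
half, MSF the minimum between them, with times HPT/MST/TOT in % stance.
For a valid M-shape this equals "first/last local maximum" but it is robust
to noise ripples; cycles whose result is not a genuine M (peak on a window
edge, valley not strictly below both peaks) are flagged unusable and
excluded. Extrema are refined to sub-grid resolution with a least-squares
parabola over ±4 grid points — a windowed fit, because the resampled curve
is piecewise linear with a kink at the true extremum, where the classic
3-point formula mis-centers. Summary statistics (means and CVs of all six
quantities per foot) are computed across per-cycle values, *then*
aggregated — extracting from the averaged curve first would destroy the
cycle-to-cycle variability the CVs measure.

# Group statistics, feature ranking, classification

`compare_groups()` applies tie-corrected Kruskal–Wallis tests per parameter
and, when the omnibus test is significant at 0.05, pairwise Wilcoxon
rank-sum tests; no multiplicity correction is applied anywhere. Constant
parameters are flagged, not tested.

`relieff_rank()` implements ReliefF for class responses (k nearest hits and
per-class misses for every anchor instance, range-normalized Manhattan
distance, miss terms weighted by class priors) and the RReliefF extension
for continuous responses (k nearest neighbors with exponential rank weights,
relevance from the probabilities of differing in feature and response). All
instances serve as anchors — at n ≈ 39 determinism beats subsampling.
Neighbor ties are broken by instance order, so results are reproducible.
`rank_gait_predictors()` ranks predictors of the four PD-differentiating
parameters (DST CV, GA, phi deviation, PCI) per group with k = 10, excluding
each response and its algebraic components from its own pool and adding the
clinical variables (UPDRS-III, MMSE, LEDD, disease duration, affected side)
for the PD group only. The continuous responses require the regression
variant; plain ReliefF cannot score them. Reported weights include
non-positive ones (flagged) — any truncation rule for display would be
arbitrary.

`fit_lda()` is classical LDA with pooled full covariance and empirical
priors. With more predictors than training subjects (datasets III and IV:
52 and 56 predictors, 38 training subjects per leave-one-out fold) the
pooled covariance is singular; so is dataset I's, through the exact linear
identities inside the kinematic set (`PCI = phi CV + phi deviation`,
`PST + PSWT = 100` per foot). In these cases a ridge of
`1e-6 × mean diagonal` is added with a warning. `loo_cross_validate()` holds out one subject per fold,
fits z-score standardization on the training fold only, and accumulates a
confusion matrix; ACC is trace/total and SEN/SPE are macro one-vs-rest
averages, the only well-defined single-number choice for a 3-class problem.
The four predictor datasets are I kinematics (28), II kinetics (24),
III both (52), IV four demographics (age, sex 0/1, weight, height) + both
(56); clinical variables are never classification predictors because
controls lack them.

# The synthetic cohort

No subject-level recordings are deposited with the study this pipeline
models, so validation uses a generator whose defaults encode the study
conditions: 16 young controls (YC), 12 age-matched controls (AMC), 11
medicated Parkinson's patients (PD); 5-min two-insole recordings at 100 Hz
on a 25 m walkway with a turn every ~17 strides.

**Timing model** (`generate_stride_schedule()`). Left stride durations are
drawn i.i.d. normal; swing scales *proportionally* with the realized stride
plus an additive residual, so tempo fluctuation stretches the whole cycle
rather than loading entirely onto double support (with absolute swing
draws, emergent DST CV came out near triple the intended values). Both
legs' swing fractions use the left (generating) leg's stride mean as
denominator: interleaved right strikes necessarily realize the left
stride-time mean, and per-leg denominators would distort the intended swing
asymmetry. Right strikes are placed within each left stride at the
subject's phase set-point plus per-stride phase noise, so phase and
double-support variability are independently controllable; extra toe-off
jitter (`double_support_sd_s/√2` per toe-off) drives DST variability.
Turns inflate one left stride by U(1.5, 2.5) and scale its force by 0.8;
on the right leg the inflation necessarily smears over the two strides
straddling it, and the ground truth records exactly those indices.

**Stance curve** (`synth_stance_curve()`). Quarter-sine contact edges and
raised-cosine interior segments through (0,0) → (f1, HPF) → (f2, MSF) →
(f3, TOF) → (1,0). Each segment is strictly monotone, so the curve has
exactly two maxima and one interior minimum at exactly the landmark
fractions and magnitudes; every extremum has quadratic (locally parabolic)
tangency, as in measured GRFs. This family was chosen over Gaussian-bump
mixtures (whose extrema shift when bumps overlap) and over cubic Hermite
segments (whose one-sided cubic tangency at the peaks biased smoothed and
refined peak-time estimates by about 2% of stance). The healthy template
puts landmarks at 26/46/74% of stance with magnitudes 0.95/0.62/1.10 BW.

**Group profiles** (`default_profiles()`). Timing medians follow the
study's group tables (stride ≈ 1.12–1.14 s, swing ≈ 0.37–0.38 s). The PD
deficits are: double-support jitter 22 ms vs 4–6 ms in controls; swing
asymmetry ln-ratio 2.8% vs 0.9% (YC) and 2.2% (AMC); and a *lateralized*
phase set-point — each PD subject's phase offset is `±(3.5° + |N(0, 1.5°)|)`
with random sign, emulating the asymmetric clinical onset. The lateralized
form is deliberate: the printed PD phase CV (≈1.5%) and phase deviation
(≈2.6%) are jointly consistent only with set-point offsets of consistent
magnitude, and a zero-centered Gaussian makes an 11-subject group median
unstable. Phase and double-support parameters were calibrated so that the
*emergent* group medians of the full measurement chain — including 10 ms
event quantization, which contributes about 2° of apparent phase noise —
approximate the study's printed medians. Between-subject spreads (3%
common timing scale, 0.25% per-leg swing perturbation, lognormal 0.15 on
jitter magnitudes, demographic draws truncated at plausible floors) are
kept modest: some printed between-subject sds include heavy tails that
would make group medians of 11–16 subjects non-reproducible, and the
directional group findings are the quantity the generator must preserve.
PD double-support jitter is additionally coupled to disease duration
(`×(1 + 0.35·z)`), emulating the dependence of double-support variability
on clinical status that the feature-selection analysis should recover.

**What the generator does not emulate**: freezing of gait, festination or
falls; spatially resolved 954-sensor pressure maps (the coarse grid emitter
exists only to exercise the reader); drift, saturation or calibration error
in the insoles; within-walk fatigue trends; and correlated left/right
neuromotor noise beyond the phase coupling above. A passing test suite
therefore shows the pipeline recovers known structure of this generative
family — it does not certify performance on real insole recordings.

# Numerical choices and degenerate inputs

Sampled-curve magnitudes hit the template within well under 1% (flat
extrema); stances shorter than 5 samples are rejected (generator) or
skipped with a count (segmentation). An all-zero series yields an empty
event list; a series that never drops below threshold raises "no swing
phase detected". Constant predictors get ReliefF weight 0 and are flagged;
k is truncated with a warning when a class is smaller than k. Swing-time
ties in the phase reference choice go to the left leg with a warning. CVs
require n ≥ 2 and non-zero mean. Zero-variance, zero-noise cohorts
propagate to exactly zero CVs, GA = 0, phi = 180 and PCI = 0, which the
test suite asserts end-to-end.

# Problem sizes used in the test suite

Deterministic recovery checks use 40–90 s recordings (35–80 strides); the
Monte-Carlo detection and direction checks use 90–120 s recordings over
10–20 seeds; the structural and qualitative cohort checks run the full
39-subject, 5-min default cohort once, plus twenty reduced-analysis
replicates (feature extraction and two LOO classifications each). These
sizes give stable medians: CV-type statistics stabilize within a few
percent beyond ~50 strides, and doubling the replicate count changes none
of the pass/fail margins.

# Known limitations

Event times at 10 ms resolution put a floor under phase CV (~1%) and make
per-foot PST biased by up to half a sample of stance; with typical adult
stride times this is ≤0.5% of the gait cycle. DST here sums both
double-support intervals per stride (~0.33 s for healthy timing);
single-interval conventions (~0.17 s) differ by a factor of 2 in mean but
not in CV. RReliefF weights depend on the neighbor-weighting kernel; the
exponential rank kernel with sigma = k is fixed and documented, and only
weight *orderings* should be compared across implementations. The LDA ridge
on datasets III/IV makes those accuracies sensitive to the regularization
scale — the package treats them as structural outputs, not headline
numbers.
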