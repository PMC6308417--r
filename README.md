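# insolegait

Gait analysis for free walking recorded with pressure-sensitive in-shoe
insoles, aimed at quantifying how Parkinson's disease (PD) alters bilateral
coordination. From two per-foot vertical ground-reaction-force (GRF) time
series sampled at 100 Hz, the package detects gait events, removes turn
strides, and computes 28 kinematic and 24 kinetic parameters per subject;
it then compares groups, ranks predictors of the coordination deficits, and
classifies group membership. A synthetic-cohort generator with complete
ground truth stands in for the study data (which are not deposited), so
every stage is testable against known truth.

Intended users: movement-science and wearable-sensor researchers analysing
insole or force-plate walking data in R, and anyone needing a fully
synthetic but statistically realistic two-insole gait benchmark.

## The measures at the core

For each foot, foot-strike and toe-off events partition the signal into
stance and swing. Per stride the package computes stride/stance/swing
times, their coefficients of variation (CV = 100·sd/mean), double-support
time (DST, the bilateral-contact time per stride window) and its CV.
Bilateral coordination is summarized by

- gait asymmetry `GA = 100·|ln(SSWT/LSWT)|` over the two legs' mean swing
  times,
- the phase of each contralateral strike within the reference stride,
  `phi_i = 360·(t_Si − t_Li)/(t_L(i+1) − t_Li)` (180° = ideal alternation),
- the phase coordination index `PCI = phi CV + phi deviation`, with
  `phi deviation = 100·mean|phi_i − 180|/180`.

The stance GRF is M-shaped; per cycle the heel-peak, mid-stance and
toe-off forces (HPF/MSF/TOF, body-weight fractions) and their times in
% stance (HPT/MST/TOT) are extracted, plus the CVs of all six. Group
comparisons use Kruskal–Wallis with Wilcoxon post-hocs, feature ranking
uses ReliefF/RReliefF (k = 10), and classification uses leave-one-out
linear discriminant analysis on four predictor sets (kinematics, kinetics,
both, demographics + both).

## Worked example

```r
library(insolegait)

# simulate the default 39-subject cohort (16 YC, 12 AMC, 11 PD; 5-min
# two-insole recordings at 100 Hz) and run the full analysis (~40 s)
res <- run_pipeline(pipeline_config(seed = 1))

dplyr::select(res$comparisons, parameter, median_YC, median_AMC, median_PD,
              chi_square_kw, p_value) |>
  dplyr::filter(parameter %in% c("DST CV", "GA", "PCI"))
#> # A tibble: 3 x 6
#>   parameter median_YC median_AMC median_PD chi_square_kw     p_value
#>   <chr>         <dbl>      <dbl>     <dbl>         <dbl>       <dbl>
#> 1 DST CV        6.11        6.02      7.30          16.3 0.000285
#> 2 GA            0.684       2.31      2.87          28.0 0.000000834
#> 3 PCI           2.66        2.98      4.91          21.8 0.0000184

dplyr::bind_rows(lapply(res$classification, glance))
#> # A tibble: 4 x 6
#>   dataset n_folds   acc   sen   spe n_regularized
#>   <chr>     <int> <dbl> <dbl> <dbl>         <int>
#> 1 I            39  87.2  85.8  93.9            39
#> 2 II           39  38.5  36.6  69.1             0
#> 3 III          39  69.2  68.2  85.4            39
#> 4 IV           39  61.5  58.6  81.7            39
```

The comparison table reads as in a clinical gait study: on this cohort the
simulated PD group shows raised double-support-time variability (7.30 vs
~6.1), larger gait asymmetry and a higher phase coordination index, all
significant by Kruskal–Wallis, while kinetic (force-shape) parameters do
not separate the groups — so kinematic predictors (dataset I, 87% accuracy
over 39 leave-one-out folds) classify far better than kinetic ones
(dataset II, near the 33% chance level). `n_regularized` counts folds
where the pooled covariance needed the small ridge; for dataset I that is
every fold, because the kinematic set contains exact linear identities
(PCI = phi CV + phi deviation, PST + PSWT = 100). `autoplot(res$classification$I)`
draws the confusion matrix; `plot_grf()` and `plot_average_cycle()` show a
recording with its detected events and the group-average M-shaped stance
curve.

To analyse real recordings instead of simulations, read each foot with
`read_grf_csv()` (columns `time_s,force`), the subject table with
`read_subject_table()`, and call `extract_gait_features()` per subject.

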