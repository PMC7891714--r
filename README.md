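# nirsload

Multi-distance fNIRS analysis of cognitive workload and motor-skill level,
with a first-class synthetic cohort generator.

## The problem

High-density continuous-wave NIRS devices record light attenuation at two
wavelengths (780 / 850 nm) across hundreds of source-detector channels
whose separation distance (1.5, 2.12, 3.0, 3.35 cm) controls sampling
depth: short channels see mostly scalp and skull hemodynamics, long
channels reach the cortex. During standardised laparoscopic training
tasks, prefrontal cortex (PFC) activation differs between novices and
expert surgeons and tracks subjective task load (NASA-TLX). This package
implements the full analysis chain used in that paradigm:

1. **MBLL** — optical-density changes to chromophore concentration
   changes, `dOD(l) = [e_HbO(l) dHbO + e_HbR(l) dHbR] d DPF(l)` with
   DPF(780) = 5.075, DPF(850) = 4.64;
2. **Band-pass** — zero-phase Butterworth, 0.01–0.5 Hz;
3. **Motion artifact rejection** — per channel, SD over non-overlapping
   10 s windows; windows with SD > median + 4.5 x MAD are excluded;
4. **Activation features** — window-SD of dHbO averaged per task episode,
   optionally after superficial signal regression (SSR) of the nearest
   1.5 cm channel out of each 3 / 3.35 cm channel;
5. **Group statistics** — within-group median-split load labels,
   Wilcoxon / KS comparisons over (separation class x hemisphere) cells
   with Bonferroni control at `p < alpha / k` (alpha = 0.05, k = 16), and
   topographic (Delaunay barycentric) interpolation of channel maps;
6. **Classification** — features ranked by |Pearson r| with the labels, a
   linear SVM evaluated by subject-grouped, stratified 5-fold CV at
   increasing feature counts, and a **selection-in-the-loop permutation
   null**: every label shuffle repeats the feature selection, which is
   what biases the null above 50 % at small feature counts.

No raw recordings from the original study are public, so the
`simulate_cohort()` generator produces cohorts (17 students, 11 attending
surgeons by default) with the statistical structure the analysis assumes;
every downstream stage is tested against it.

## Worked example

```r
library(nirsload)

study <- default_study_config()
study$schedule$task1_s <- study$schedule$task2_s <- 120  # quick demo
cohort <- simulate_cohort(study, seed = 101, ground_truth = "none")
features <- cohort_features(cohort)

print(compare_groups(features, "skill", observations = "subjects"), digits = 4)
#>   class_cm hemisphere n_channels statistic         p    delta significant
#> 1     1.50          L         26       126 0.1322490 0.003559       FALSE
#> 2     2.12          L         18       131 0.0817723 0.008894       FALSE
#> 3     3.00          L         34       155 0.0041117 0.051477       FALSE
#> 4     3.35          L         24       164 0.0009919 0.091943        TRUE
#> 5     1.50          R         26       106 0.5724244 0.002474       FALSE
#> 6     2.12          R         18       130 0.0903691 0.006782       FALSE
#> 7     3.00          R         34       148 0.0110795 0.031206       FALSE
#> 8     3.35          R         24       153 0.0055137 0.053466       FALSE
```

Students carry a planted higher task-evoked amplitude, which surfaces as
a higher window-SD activation (`delta` > 0, in uM) that grows with
separation distance and reaches the Bonferroni threshold
(p < 0.05/16 = 0.003125) in the deepest (3.35 cm) left-hemisphere cell —
short channels are dominated by the shared superficial signal, and the
planted student activation is left-lateralised. Classification of skill
from the 3.35 cm channels, with its permutation null:

```r
task1 <- features$row_meta$episode == "task1"
cols <- which(features$col_meta$class_cm == 3.35)
X <- features$values[task1, cols]
lab <- features$row_meta$group[task1]
sid <- features$row_meta$subject_id[task1]
curve <- accuracy_curve(X, lab, sid, c(1, 2, 4, 8, 16), n_reps = 100, seed = 5)
null <- permutation_null(X, lab, sid, c(1, 2, 4, 8, 16), n_perms = 100, seed = 6)
cbind(curve$curve, null_mean = null$null$mean)
#>   n_features      mean         sd null_mean
#> 1          1 0.8142095 0.02124018 0.6049048
#> 2          2 0.8070286 0.02415764 0.6065714
#> 3          4 0.8145333 0.03243597 0.5983905
#> 4          8 0.8116000 0.02426685 0.5808857
#> 5         16 0.7939810 0.02973481 0.5605333
```

The accuracy curve (~0.81 at its peak) sits well above the null — note
the null itself is ~0.60, not 0.50, precisely because feature selection
is repeated inside the permutation loop.

An end-to-end run (simulate, preprocess, features, statistics, both
classification targets, manifest) is one call:

```r
res <- run_study(default_pipeline_config(), out_dir = "out")
```

or from the shell via the bundled CLI (`exec/nirsload`):

```sh
nirsload run --seed 1 --out out
nirsload simulate --seed 1 --out cohort_dir
```

## Scope notes

Diffuse optical tomography, SNIRF/HDF5 export, mRMR / Chi-square feature
selection and hardware control are out of scope. See
`vignettes/nirsload-methods.Rmd` for the model, its assumptions, and the
design decisions.
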