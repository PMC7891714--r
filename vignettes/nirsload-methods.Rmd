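---
title: "nirsload: models, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nirsload: models, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement model, the analysis chain, the synthetic world the tests
run against, and the places where the design was genuinely open and a
choice had to be made.

# The measurement model

A continuous-wave NIRS channel is a source-detector pair. Light
attenuation changes at two wavelengths relate to oxy- and
deoxy-hemoglobin concentration changes through the modified Beer-Lambert
law,

$$\Delta OD(\lambda) = \left[\varepsilon_{HbO}(\lambda)\,\Delta HbO +
\varepsilon_{HbR}(\lambda)\,\Delta HbR\right] d\,\mathrm{DPF}(\lambda),$$

with $d$ the source-detector separation and DPF the differential
pathlength factor (5.075 at 780 nm and 4.64 at 850 nm by default). Per
sample and channel this is a $2\times2$ linear system; `mbll_invert()`
solves it directly, and `forward_mbll()` is the same relation run
forwards (used by the simulator). The extinction coefficients are a
standard compiled tabulation stored in `default_extinction_matrix()`;
because no analysis result depends on their particular values, all
correctness tests are forward/inverse round-trip tests (relative error
$<10^{-9}$), never comparisons against specific $\varepsilon$ values.

The montage has 204 channels in four separation classes (52 at 1.5 cm,
36 at 2.12 cm, 68 at 3.0 cm, 48 at 3.35 cm). Separation controls
sampling depth: 1.5 cm channels see almost exclusively scalp/skull
("superficial") hemodynamics; 3–3.35 cm channels carry a substantial
cortical contribution on top of the same superficial signal. The true
optode geometry of the device is not public and no downstream
computation needs it — only the class label, the hemisphere, and rough
midpoint proximity (for pairing short channels to long ones) are used —
so `build_layout()` places midpoints on a deterministic grid spanning
about ±6 cm, with regions (dorsolateral, ventrolateral, medial,
orbitofrontal) assigned by position. The grid guarantees every long
channel has a 1.5 cm channel within 3 cm.

# Preprocessing

* **Band-pass 0.01–0.5 Hz.** The filter family is not dictated by the
  analysis description; we use a Butterworth design (prototype order 4,
  so 8 poles) applied forward and backward (`filtfilt`) with odd end
  padding and steady-state initial conditions. Zero phase matters
  because the features are windowed statistics: phase distortion would
  move energy across window boundaries. The design was validated against
  an independent reference implementation (scipy.signal): coefficients
  agree to $10^{-12}$, filtered output to $\sim 4\times10^{-4}$
  relative. The contract tested is behavioural: DC annihilated, $\le$
  1 dB ripple at 0.1 Hz, $\ge$ 20 dB attenuation at 1 Hz (cardiac).
  Mayer waves (~0.1 Hz) are inside the band and deliberately not
  removed.
* **Motion artifacts.** Per channel, the SD of each complete
  non-overlapping 10 s window is computed; with $m$ the median of those
  SDs and MAD their raw median absolute deviation, windows with
  $SD > m + 4.5\,\mathrm{MAD}$ are excluded. Two interpretive points:
  only *high-side* excursions are flagged (a quiet window is not an
  artifact), and the rule is applied over the whole recording by
  default (per-episode application is a parameter away, via
  `detect_artifact_windows()` on episode slices). Flagged windows are
  dropped from feature averaging, never interpolated. A zero MAD
  (constant-variance degenerate channel) flags nothing and warns.
  Filtering happens *before* detection, so the rule sees the same series
  the features are computed from; consequently the "$\ge 10\times$
  background" sensitivity property is stated in the filtered domain —
  the band-pass legitimately absorbs much of a sharp transient's energy.

# Features

The activation measure is the **within-window SD of $\Delta$HbO**
(10 s windows), averaged over the retained windows lying fully inside a
task episode; a greater evoked response produces larger excursions
within windows, which this statistic captures where a window mean would
not. Window mean, skewness and kurtosis are available
(`window_statistic()`) but nothing downstream uses them. Only HbO is
featurized; HbR is simulated and preprocessed but not analysed,
mirroring the reference analysis. Channels with fewer than 3 retained
windows in an episode are missing and imputed with the column median
(an invented policy — the reference analysis never mentions
missingness; the imputation is logged and marked in the returned
object).

**Superficial signal regression (SSR).** For each 3 / 3.35 cm channel
the regressor is the *nearest* 1.5 cm channel (ties broken by lowest
channel id), $\beta$ is the whole-recording least-squares projection
coefficient, and the channel is replaced by its residual. Pairing rule
and fit span are unstated in the reference methodology; nearest-single-
channel over the whole recording is the simplest deterministic
instantiation. SSR is applied after band-pass filtering so both series
share a spectral support.

# Group statistics

Load labels are a **within-group median split** of the NASA-TLX mean
score (mean of the six 1–20 subscales), separate cut-offs per group,
ties at the median going "low" (deterministic convention). Comparisons
are organised in (separation class × hemisphere) cells; the Bonferroni
family constant is $k=16$ with $\alpha=0.05$ ($p < 0.003125$). Note the
cell arithmetic: 4 classes × 2 hemispheres is 8 cells per task; the
family of 16 corresponds to the two task episodes together
(`compare_groups(episode = c("task1", "task2"))`), and the constant 16
is used even when a single task is analysed, which is conservative.

One genuinely open design point deserves emphasis. The descriptive
figures treat *channels* as the paired observations (each channel's
group-mean activation on one side vs the other, Wilcoxon signed-rank).
Implementing this revealed it to be **anti-conservative**: all channels
of a cell share each subject's common activation fluctuation (amplitude
variability, event-count variability, the shared superficial signal),
so under a true null the paired differences share a common-mode offset
and the signed-rank test fires on noise (we measured 6–13 "significant"
cells of 16 on zero-effect cohorts). `compare_groups()` therefore
offers two modes: `observations = "channels"` (faithful to the
descriptive figures; default) and `observations = "subjects"`, which
averages each subject's activation over the cell's channels and
compares the two independent subject samples with a Wilcoxon rank-sum
test. The subjects mode is calibrated (zero-effect cohorts yield
essentially zero significant cells) and is what the parameter-recovery
tests use. Both are Wilcoxon tests with the same Bonferroni control;
they differ only in what counts as an observation.

`topographic_map()` interpolates channel values linearly (Bowyer-Watson
Delaunay triangulation + barycentric interpolation, implemented in the
package since no triangulation library is available in the target
environment) onto a regular grid, masked outside the convex hull.

# Classification

Rows of the feature matrix are subject-episodes; columns are channels.
Features are ranked **once on the full matrix** by $|r|$ (Pearson
correlation with the binary labels), then a linear SVM (C = 1,
per-training-fold standardisation) is evaluated by 5-fold CV at
increasing feature counts, each count repeated with fresh fold
partitions (2000 repetitions at full scale; `n_reps` is scalable and
100 is ample for the curve mean at desk scale). Folds are grouped by
subject *and* stratified by class, reconciling "5-fold" with the
guarantee that a training-set subject never appears in the test set.
The SVM itself is an L2-regularised hinge-loss dual coordinate-descent
solver compiled in the package (no SVM library exists in the target
environment); on separable data it reaches accuracy 1 and it is
deterministic given the data.

**The permutation null is the heart of the study.** For each of the
permutations the labels are shuffled and the *entire* analysis — feature
ranking included — is re-run on the surrogate labels. Because spuriously
correlated features are re-selected on every shuffle, the null mean sits
far above 50 % at small feature counts (~79 % at 4 of 204 features on a
30-row pure-noise matrix) and returns to 50 % when all features are
included and selection is vacuous. Two subtleties we established and
froze into tests:

* the null is **not monotone** in the feature count: it *rises* while
  added features are still spuriously selected (~0.76 at $n=2$ to ~0.88
  at $n=32$ on 30×204 noise) and only collapses to 0.5 at the full set.
  This shape was cross-checked against an independent scikit-learn
  implementation of the identical protocol (agreement within 0.01).
* nesting the ranking inside each training fold
  (`selection = "in_fold"`) removes the bias entirely (null mean
  0.5 ± 0.03 at small $n$) — the internal control separating the two
  selection regimes.

`motion_only_classification()` is the negative control: the six
accelerometer/gyroscope traces summarised by the same window-SD /
episode-average procedure classify at chance unless a motion-rate
difference is deliberately planted.

# The synthetic world

No recordings from the paradigm are deposited anywhere, so the
generator is a first-class module and the stated world of all tests.
Per channel,

$$\Delta HbO(t) = w_c(\mathrm{class})\,A(\mathrm{region},\mathrm{hemi})\,x(t)
 + w_s(\mathrm{class})\,s_{sup}(t) + \mathrm{drift}(t) + \varepsilon(t),$$

with $\Delta HbR = -\rho\,(\text{cerebral part}) + \text{noise}$
($\rho = 1/3$), optical densities by the forward Beer-Lambert map, and
motion events injected afterwards into both the ODs and the motion
traces. Defaults and what they encode:

* **Mixing weights** $w_c = (0.05, 0.15, 0.50, 0.65)$ and
  $w_s = (1.0, 0.9, 0.7, 0.6)$ across the four classes: qualitative
  depth sensitivity (deeper channels see more cortex, less scalp). The
  ground truth stores the components, and the cerebral-to-superficial
  variance ratio is verified to increase with separation.
* **Task regressor** $x(t)$: the task boxcar convolved with a canonical
  double-gamma HRF (~6 s peak) *plus* an HRF-convolved train of
  task-locked sub-events (Poisson, 6/min during tasks, amplitude gain
  2). The event term is a deliberate extension of the plain
  boxcar⊗HRF model: a pure block response is nearly constant during the
  task plateau, so the window-SD feature would be almost blind to the
  amplitude $A$ — the activation measure presupposes within-episode
  fluctuation of the evoked response, which discrete subtask actions
  (ring transfers, threading moves) provide. The gain was set from a
  component-level decomposition (cerebral within-window SD comparable
  to the superficial term in the deepest channels), not from test
  outcomes. Linearity in $A$ is preserved and tested.
* **Superficial signal** $s_{sup}$: subject-shared sum of sinusoids at
  ~0.1 Hz (Mayer, 0.5 µM), ~0.3 Hz (respiration, 0.25 µM), ~1 Hz
  (cardiac, 0.15 µM) with per-subject frequency jitter; all below the
  4.069 Hz Nyquist limit. Being subject-shared is what makes SSR work
  in the simulation and is also the main realistic feature *limiting*
  what a green test establishes: real superficial physiology is only
  partially coherent across the scalp.
* **Group structure**: 17 students, 11 attendings; mean cerebral
  amplitude 1.0 µM vs 0.5 µM; a left-hemisphere multiplier (1.3) for
  students only; lognormal between-subject spread (SD 0.2). The latent
  load couples to amplitude via
  $\exp(0.3\,\mathrm{sign}\cdot\mathrm{load})$ with sign +1 for
  students, −1 for attendings — the expertise-reversal structure. The
  NASA-TLX subscales are an affine function of the same latent load
  plus noise, clipped to [1, 20], so the load–activation correlation
  has the group-dependent sign by construction.
* **Protocol**: 60 s rest, task (≤ 360 s; default 300 s, a typical
  completion time under the 6-minute cap), repeated twice, at
  8.138 Hz. Tests shorten tasks to 120 s — a legitimate point of the
  stated world (fast completions), reducing compute only.
* **Motion**: Poisson events (0.5/min), lognormal amplitude,
  exponential 2 s decay plus a small residual baseline shift, mirrored
  into the accelerometer/gyroscope traces so artifact/motion
  concordance is reproducible.
* **RNG**: one root seed; per-subject streams derived by a stable
  integer hash of (seed, subject id), so cohorts are bit-reproducible
  and subjects can be re-simulated in isolation.

What the generator does *not* emulate: between-group variance
differences (only means are planted), partially-coherent superficial
physiology, heterogeneous optode coupling, task-correlated motion, and
any realistic photon-transport forward model. A green test therefore
establishes that the *analysis chain* behaves as specified on data with
the assumed statistical structure — not that the assumed structure is
an accurate model of surgeons' physiology.

# Numerical choices and degenerate inputs

* filter padding: odd reflection, 24 samples, steady-state initial
  conditions; series shorter than 3 filter lengths are an error.
* SSR with a zero-variance regressor returns the channel unchanged with
  a warning; orthogonality of residual and regressor is tested to
  $10^{-8}$ relative.
* `median_split` ties go low; single-score groups warn.
* Wilcoxon p-values use the normal approximation with continuity
  correction (validated against exact enumeration at $n=12$); all-zero
  difference vectors return $p=1$ with a warning.
* KS p-values are asymptotic.
* zero-variance feature columns rank last with $r$ treated as 0; fold
  draws that lose a class are retried (at most 10 times); empty folds
  (possible when subjects < folds) are skipped.
* the topographic interpolation masks everything outside the convex
  hull and is exact at channel midpoints to $10^{-9}$.

# Scale-downs in the shipped tests

The full-scale protocol (300 s tasks, 204 channels, 2000 repetitions)
is the default configuration of the *package*; the *test suite* runs
reduced problem sizes to stay inside its time budget: 120 s tasks, a
proportionally thinned montage (about half the channels per class) for
the 20-seed cohort recovery checks, 100 CV repetitions and 100–200
permutations. Repetition counts only tighten Monte-Carlo error around
the quantities tested; no analysis constant is altered.

# Known limitations

* The temporal model of "activation" (HRF-convolved boxcar plus event
  train) is a stand-in; the original analysis never specifies one.
* The channel-paired descriptive test is anti-conservative (see above);
  its output is reproduced for fidelity, but inference should use the
  subject-level mode.
* KS and signed-rank tests are offered for overlapping comparison types
  because the source methodology uses both without a sharp mapping; the
  mapping here is configurable.
* SSR uses a single nearest short channel; multi-regressor or
  short-channel-PCA variants are out of scope.
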