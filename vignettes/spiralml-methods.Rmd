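---
title: "Methods: tremor severity analysis of digitized spiral drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tremor severity analysis of digitized spiral drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralml)
```

## The problem and the model

The Archimedes spiral test asks a subject to trace the spiral
$r = a + b\theta$ on a digitizing tablet. Essential tremor superimposes a
4–12 Hz oscillation of the hand on the intended trajectory, with a
displacement amplitude that grows with clinical severity (graded here as
level 0 = control, 1 = low tremor, 2 = high tremor, a stratification of the
Fahn–Tolosa–Marin TRS score). `spiralml` quantifies that signature along two
complementary routes:

1. **Consistency route.** Per drawing, the radius series
   $r_n = \sqrt{x_n^2 + y_n^2}$ (or the DCT-residue series, below) is
   computed on a common 4096-point grid. Within each group, the
   subjects × subjects Pearson correlation matrix of these series measures
   how interchangeable the drawings are; tremor degrades the off-diagonal
   mean and inflates its spread. The group difference in pooled off-diagonal
   values is tested with a two-sided Mann–Whitney U test, chosen because the
   correlation values are bounded, skewed and non-normal.

2. **Classification route.** The per-subject series are stacked into an
   $n \times 4096$ matrix, reduced by PCA to the smallest component set
   explaining 95% of variance, projected onto 2 linear-discriminant axes
   (the maximum for 3 classes), and classified by an RBF-kernel SVM (or
   k-NN, random forest, LDA). Validation schemes: leave-one-out, stratified
   80/20 hold-out, plain and stratified 5-fold, and stratified 5-fold after
   adding $N(0, 0.01^2)$ noise to the discriminant features.

### Assumptions

- The drawing is a single pen-down stroke (pen-up samples are discarded;
  an optional burst simulates brief lifts).
- Trajectories from different subjects are comparable after linear
  resampling onto normalized cumulative time; this assumes drawing *style*
  (speed profile) is not itself the discriminative signal.
- Tremor is an additive, approximately sinusoidal displacement; its
  frequency lies in the 4–12 Hz band and is resolvable at 200 Hz sampling.

## Feature definitions and parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| resample length `n` | 4096 | samples | common series length; 20.48 s at 200 Hz |
| smoothing `denom` | 256 | – | rolling-mean window $w = \mathrm{round}(l/\mathrm{denom})$, so $w = 16$ (80 ms) at $l = 4096$ |
| DCT truncation `k_keep` | 32 | coefficients | low-frequency reconstruction kept below ≈ 0.8 Hz for a 20 s drawing |
| PCA `var_target` | 0.95 | – | minimum cumulative explained variance |
| LDA `n_components` | 2 | axes | `min(n_classes − 1, n_pca)` |
| SVM grid | C ∈ {0.1, 1}, γ = 0.1 | – | resolved by inner 3-fold grid search on training data |
| k-NN grid | k ∈ 5..10 | – | Euclidean distance |
| random forest | 100 trees | – | seeded |
| noise σ | 0.01 | LDA-space units | robustness perturbation |

The rolling mean uses a centered window that *shrinks* symmetrically at the
series edges rather than padding, so no boundary values are invented; its
frequency response on interior samples is the classical moving-average gain
$|\sin(\pi f w/f_s) / (w \sin(\pi f/f_s))|$, which at the defaults passes
most of the tremor band (gain ≈ 0.66 at 6 Hz). `denom = 256` balances
sample-level jitter suppression against tremor-band retention; it is a free
parameter of the method and is exposed in every relevant function.

The DCT residue of a coordinate series is the remainder after subtracting
the inverse transform of its first `k_keep` orthonormal DCT-II
coefficients. `k_keep = 32` keeps the slow spiral ramp (content below
$k_{keep}/2T \approx 0.8$ Hz for a $T = 20.48$ s drawing) in the
reconstruction and leaves the tremor band in the residue; residue energy is
monotone nonincreasing in `k_keep`, so the choice trades how much slow
drawing shape contaminates the residue against how much genuine
low-frequency motor signal is discarded. The x and y residuals are combined
as the pointwise magnitude $\sqrt{res_x^2 + res_y^2}$ — rotation-insensitive
and, importantly, *rectified*: a zero-mean oscillation of amplitude $A$
becomes a series with positive mean of order $A$, so severity is encoded in
the residue's level, not only its variance. A concatenation mode is also
provided.

Z-score normalization (population sd; a constant series maps to zeros) is
available to put radius and residue features on one scale for joint
plotting. It is **off by default** in the classification path: Pearson
correlations are scale-invariant anyway, and per-series standardization
would erase the severity-scaled amplitude information the classifier uses.

## The synthetic cohort generator

Clinical spiral datasets are typically not sharable, so the package's study
conditions are defined by a simulator whose defaults are fixed once:

- **Geometry** — $a = 0.5$, $b = 1$, 5 turns, 20.48 s at 200 Hz (exactly
  4096 samples), drawn at approximately constant pen speed by inverting the
  arc-length integral. The outer radius is ≈ 31.9 device units.
- **Tremor** — injected along the local radial direction as
  $A(t)\sin(2\pi f t + \phi)$, with per-subject frequency uniform in
  4–10 Hz, random phase, and envelope jitter of 10%. Level amplitudes are
  0, 0.5% and 3% of the outer radius (≈ 0.16 and 0.96 units): the
  low-tremor condition is deliberately close to control ("very mild"),
  making the 0-vs-1 contrast the hard part of the task. Per-subject
  amplitude scatter is log-normal (sd 0.2).
- **Baseline motor noise** — every subject, including controls, receives
  smooth Gaussian drift (sd 0.3 units per coordinate) band-limited below
  0.5 Hz. Slow postural wander operates on timescales of seconds, well
  below the tremor band; keeping it below the `k_keep` cutoff also means
  the DCT residue isolates tremor rather than drift, which is what makes
  the control / low-tremor contrast learnable at all.
- **Metadata** — TRS scores are truncated-normal draws per level (means
  0 / 6 / 25, truncation at 0 reproducing the right-skew of clinical TRS
  distributions; controls score exactly 0), and ages rise with level
  (means 45 / 55 / 65 years), emulating the age–severity confound of real
  cohorts; both are configurable off. Default group sizes 29/12/12 mirror a
  29-control / 24-patient clinical sample.

Cohorts are pure functions of their configuration seed.

**What the simulator does not emulate:** biomechanics (no arm model, no
stroke-direction asymmetry), micrographia or progressive radius distortion,
intention-tremor amplitude growth toward the spiral's outer end, pressure
or pen-angle pathology, session and device effects, and any coupling
between drawing speed and severity. Consequently, passing tests demonstrate
that the pipeline recovers the *kind* of structure it assumes — band-limited
severity-scaled oscillation against smooth drift — not that it will achieve
comparable accuracy on clinical recordings.

## Numerical and design choices

- **DCT implementation**: orthonormal DCT-II/DCT-III via zero-padded FFTs
  (base R has no DCT); verified in the tests against a direct $O(n^2)$
  cosine sum and by round-trip/Parseval identities at 1e-9.
- **Mann–Whitney U**: midranks for ties; exact p by complete enumeration of
  all $\binom{n_1+n_2}{n_1}$ rank subsets when $n_1 + n_2 \le 16$ and the
  pooled sample is tie-free (the bound keeps enumeration ≤ 12870 subsets
  and provides an in-package oracle for the approximation); otherwise a
  normal approximation with tie-corrected variance and continuity
  correction. Two-sided by default, matching how such group comparisons are
  reported.
- **Correlation-matrix axis**: drawing consistency can be read subjectwise
  (subjects × subjects over time points) or timewise (time points over
  subjects). The subjectwise reading directly formalizes "how similar are
  the group's drawings" and is the default; the timewise mode is
  implemented behind the same interface (`mode = "inter_temporal"`, on a
  64-point downsampled grid — a full 4096² matrix adds nothing at these
  sample sizes).
- **Off-diagonal pooling**: summaries and the U test use each unordered
  subject pair once (upper triangle). Pooling the full off-diagonal set
  would duplicate every value without changing the ranks between groups.
  Pairs from one matrix are not independent; the test is reported as-is,
  unadjusted, and a per-subject-mean alternative can be built from the
  returned matrices.
- **Leakage policy**: by default all fitted transforms (PCA, LDA) and
  hyperparameter choices are refit inside every fold on training data
  only; `paper_mode = TRUE` instead fits the reduction once on the full
  dataset before splitting. The optimistic mode is shipped deliberately so
  both protocols can be inspected side by side; train scores of 100% under
  cross-validation are a signature of the second protocol.
- **Metric conventions**: macro (unweighted per-class one-vs-rest)
  averaging for precision/recall/F1, percentages; zero-division → 0 with a
  warning; confusion rows are the true classes. Weighted averaging is a
  flag. Under leave-one-out, the train score is the mean over folds of the
  training-set metrics; the test score pools all fold predictions into one
  confusion matrix.
- **Classification feature kind**: severity recovery is quoted on DCT
  residues. A purely radial random-phase oscillation leaves class *means*
  of the raw series untouched (only variances differ), which a linear
  PCA→LDA stage cannot separate; the residue magnitude rectifies the
  oscillation into a severity-scaled level, and it is also the feature with
  the strongest reported performance in comparable studies. Radius features
  carry the consistency analysis and remain available to the classifier.
- **Degenerate inputs**: constant series are rejected in correlation and
  `pearson_r` (undefined), mapped to zeros in normalization (logged);
  singular within-class scatter falls back to a ridge-regularized LDA
  (reported); k-NN tie-breaks are pinned by a fold-derived seed so reports
  are reproducible; hold-out uses a stratified 80/20 split; grid-search
  ties resolve to the first (smallest) candidate.
- **Problem sizes**: the package's own checks run on cohorts of 53
  (29/12/12, the clinical-sized configuration) and 60 (20 per level) at
  4096 samples per drawing, with ten independent seeds for the
  cohort-level properties — sizes at which every documented property is
  stable yet a full run stays interactive.

## Limitations

- Synthetic validation only: see the simulator's non-goals above. Clinical
  deployment requires recalibrating amplitudes, drift and `k_keep` against
  real recordings.
- The severity labels are generative: the simulator defines levels by
  construction rather than deriving them from a TRS threshold; a
  threshold-based deriver would sit naturally on the loader but is not
  shipped because no published cut-offs separate the strata.
- The two unadjusted U tests (radius, residue) replicate common reporting
  practice; no multiplicity correction is applied.
- With 2 discriminant features and small cohorts, SVM hyperparameters are
  barely identifiable; the tiny Table-style grid is retained for
  comparability, not because it is optimal.
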