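---
title: "Methods: nonparametric permutation mapping of Go/NoGo BOLD responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonparametric permutation mapping of Go/NoGo BOLD responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`permbold` analyzes event-related Go/NoGo fMRI at three levels — subject,
group, and group difference — using permutation inference throughout, and
ships a synthetic cohort generator so every stage is verifiable against a
known ground truth. This vignette documents the model, the parameters
that matter, the numerical conventions, and what the synthetic data do
and do not establish about behavior on real scans.

## Task structure and the performance matrix

One trial is triggered by every EPI volume acquisition, so trials and
volumes share a clock: `task_config()` defaults to n = 200 volumes at
TR = 2 s with a 20% NoGo fraction (40 NoGo, 160 Go). Each trial ends in
exactly one of four outcomes — correct Go, correct NoGo, omission,
commission — encoded as the one-hot rows of the n x 4 performance matrix
Z. Row sums of 1 are enforced as a class invariant because the
permutation scheme depends on it: shuffling the rows of Z preserves the
column sums (the subject's realized accuracy) while breaking the
link between outcomes and acquisition times.

## Subject-level model

At each voxel the BOLD series is fit by ordinary least squares against an
n x 11 design: one principal-component nuisance time course, six
rigid-body motion series, and four HRF-convolved event regressors. Two
conventions deserve comment.

**Implicit intercept.** No intercept column appears in the design;
instead the response and every design column are mean-centered before
fitting, and the residual degrees of freedom are `df = n - 1 -
rank(X'X)` — the centering consumes the one degree of freedom an
intercept would. For the standard full-rank 200 x 11 design this gives
df = 188. Centering also makes the event block of X'y computable as a
group-sum of a precomputed correlation matrix, which the compiled
permutation engine exploits.

**Pseudo-inverse.** The normal equations are solved through the
Moore-Penrose pseudo-inverse of X'X (singular values below 1e-10 of the
largest are treated as zero), so rank-deficient designs — duplicated or
zero regressors, degenerate simulations — degrade gracefully rather than
failing. Voxels where both the contrast estimate and the residual
variance vanish have an undefined 0/0 statistic; `subject_map()` sets
them to zero and reports a count. A zero-residual voxel with a nonzero
contrast estimate (possible only in noise-free simulation) is flagged as
a signed infinity.

**HRF.** The kernel is a single gamma density parameterized by its mode
(`peak_seconds`, default 6 s) and scale (`dispersion`, default 0.7 s,
giving a width of roughly 5 s FWHM), sampled at TR resolution over 16
samples (32 s) and scaled to unit peak. These values are conventional
for adult visual/motor paradigms and are fully configurable; the
pipeline's inference is permutation-based, so moderate HRF mismatch
costs sensitivity, not validity. A degenerate length-1 kernel is defined
as a unit impulse (the gamma density is zero at t = 0, so unit-peak
scaling would otherwise be undefined).

**Contrast.** The default contrast is -1 on the correct-Go regressor
(column 8) and +1 on the correct-NoGo regressor (column 9): the
successful-inhibition versus successful-response comparison. Error
regressors are modeled but not contrasted.

## Group map

Subject maps (already voxel-aligned in the synthetic common space) are
smoothed with an isotropic 3 mm-SD Gaussian — the per-axis SD in voxels
is `3 / voxel_size`, so the default anisotropic 2.5 x 2.5 x 3.5 mm grid
gets anisotropic voxel-space kernels — truncated at 4 SD. The grid
boundary is zero-padded and the kernel renormalized over in-grid
support, which preserves constant maps exactly and avoids spurious
deactivation at the brain edge. Smoothing uses the SD parameterization
directly (not FWHM).

The group map is the voxelwise **median** across subjects, chosen over
the mean for outlier resistance; with an even subject count the midpoint
of the two central order statistics is used. Smoothing precedes the
median; the operations do not commute and the order is fixed and tested.

## Permutation thresholds and clusters

Under the null hypothesis that BOLD responses are unrelated to the trial
outcomes, each subject's Z rows are exchangeable. `null_distribution()`
therefore repeats the entire subject-to-group pipeline B times (default
1000) with an independent uniform row permutation drawn per subject per
run, recording the group-map maximum and minimum inside the intersection
brain mask. All permutations derive from one master seed (drawn
subject-major), so a study is bit-reproducible.

Thresholds are order statistics chosen to make the empirical exceedance
probability *strictly* less than alpha: the upper threshold at level
alpha is the `B - ceiling(alpha * B) + 1`-th order statistic of the
maxima (equivalently `ceiling((1 - alpha) B)` whenever `alpha * B` is not
an integer — the strict version differs by one position exactly at
integer `alpha * B`), and lower thresholds mirror this on the minima.
Each tail is controlled at alpha separately, which is the guarantee the
maxima/minima construction provides; a two-tailed union test would
operate near 2 alpha. With B = 199 and alpha = 0.05 the exchangeability
argument makes the per-tail familywise rejection probability exactly
10/200 = 0.05 on null data, which the acceptance suite verifies over 200
replicate simulated studies.

`threshold_map()` labels voxels by the most stringent tier passed
(+/-1, 2, 3 for 0.05, 0.01, 0.001 by default) and `extract_clusters()`
keeps connected components strictly larger than 100 mm^3, computed
separately for positive and negative labels so opposite signs never
merge. Connectivity defaults to 18 (faces + edges); 6 and 26 are
available, and the choice is exposed because no convention is universal.

## Group differences: PC scores and sparse PCA

The response matrix R (subjects x significant voxels at the 0.05 tier)
is column-centered — scores must have zero mean, which pins the centering
convention, while voxel variances are deliberately *not* standardized (a
voxel's response amplitude is the signal of interest) — and decomposed by
SVD. Scores u_k are rescaled to unit variance; each component's sign is
fixed so its largest-magnitude loading is positive, making score
directions reproducible. Mann-Whitney U tests compare u1..u10 between
groups; the U statistic counts group1-below-group2 pairs (ties halved),
with exact p-values when n1 n2 <= 400 and no ties, and the
tie-corrected normal approximation otherwise. The ten raw p-values are
reported without multiplicity adjustment — the screening is
per-component and a familywise correction across the ten tests is the
caller's choice (see `bonferroni_adjust()`).

Sparse localization uses rank-1 penalized matrix decomposition:
maximize u'Rv subject to unit l2 norms and an l1 bound `||v||_1 <= c`,
by alternating updates where the v-step soft-thresholds R'u at the
smallest level satisfying the bound (found by bisection). Iteration
starts from the dense first component and stops when the objective's
relative change falls below 1e-6 or after 200 iterations. `c = sqrt(p)`
is inactive (dense PC recovered to 1e-6); `c = 1` forces a single
nonzero loading. Because practitioners usually think in support sizes, a
`target_nnz_fraction` interface finds c by bisection; the attainable
support sizes are quantized, so the achieved count can differ from the
target by a few voxels. Only the first sparse component is computed —
the localization question concerns the leading group-difference pattern.

## The synthetic cohort generator

The generator is the package's stand-in for an acquired two-group cohort
and defines the study conditions under which the pipeline is validated:

* 200-volume runs at TR 2 s, one trial per volume, 80/20 Go/NoGo;
* per-group response accuracies defaulting to the group means of the
  cohort table shipped with the package (control: Go 0.89, NoGo 0.94;
  case: Go 0.91, NoGo 0.85);
* a 16 x 16 x 12 grid of 2.5 x 2.5 x 3.5 mm voxels (the EPI voxel size
  of the emulated acquisition), so mm^3 cluster filtering is exercised
  with anisotropic voxels;
* gamma-HRF-shaped responses to correct-NoGo events in three compact
  regions (18 voxels, roughly 390 mm^3 each), with amplitude 1.0
  noise-SD units in group 1 and 0.5 in group 2 — a 0.5-noise-SD
  activation deficit in the case group;
* baseline 100 signal units, i.i.d. Gaussian noise (SD 1), a one-cycle
  cosine drift (amplitude 1), and motion-correlated structured nuisance:
  six centered Gaussian random-walk motion series (step SD 0.02 mm /
  0.01 degrees) injected into every voxel through small random spatial
  weights (SD 0.3);
* per-subject seeds derived as master seed + subject index, so cohorts
  are reproducible and subjects independent.

The nuisance levels are chosen so that the motion and PC regressors do
real work in the fit without dominating the event signal — the paper-level
sources give no values for them, and they are exposed as `cohort_spec()`
parameters. What the generator deliberately omits: image-level motion
(motion enters as a nuisance series and correlated signal, not as
resampling), susceptibility distortion and registration error (subjects
are generated in a common space), physiological noise and temporal
autocorrelation. Passing tests therefore establish the statistical
machinery — calibration, recovery, determinism — not robustness to
acquisition artifacts.

## Validation scales and design choices

The acceptance suite runs two large simulations sized to complete in
minutes on one CPU: FWER calibration uses 200 replicate null studies of
12 subjects on the 16 x 16 x 12 grid with B = 199 permutations (each
tail's rejection count is checked against the central 95%
binomial(200, 0.05) interval), and parameter recovery uses 25 replicate
cohorts of 2 x 15 subjects with the default deficit, requiring cluster
coverage of at least 80% of truly active voxels, a significant u1
separation with the case group scoring lower, and sparse-PCA support
enrichment in true-effect voxels, each in at least 20 of 25 replicates.
The permutation engine's compiled core is held to the plain-R reference
implementation (`subject_map()` + `smooth_map()` + `median_map()`) by
equivalence tests at 1e-8 to 1e-10.

Cohort-table statistics are computed from (n, mean, SD) summaries so
published tables can be checked without raw data. The homogeneity
pretest deciding between pooled and Welch variants is a two-sided F test
at 0.05. One data note: in the cohort summary table shipped under
`inst/extdata/`, recomputing the Go and NoGo accuracy rows from their
own summaries yields each other's published test statistics — the two
rows' t/df pairs appear swapped in the source table — so accuracy-row
statistics should be recomputed rather than quoted.

## Known limitations

* Ordinary least squares with no prewhitening: temporal autocorrelation
  in real fMRI noise is not modeled (the permutation null, which
  permutes outcome labels rather than time points, remains valid under
  the exchangeability of Z rows, but subject-level t values are not
  t-distributed and are treated only as activation indices).
* No slice-timing correction or sub-TR onset jitter: trial onset equals
  volume onset by design.
* No intersubject registration: inputs to the group stage must already
  be voxel-aligned.
* Sparse PCA is rank-1; higher sparse components are out of scope.
* The minimum cluster volume (100 mm^3) is strict and volume-based;
  cluster-mass and TFCE-style statistics are not implemented.
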