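---
title: "Dynamic ALFF analysis: models, parameters and design choices"
author: "dynalff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic ALFF analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynalff)
```

## The measure

The amplitude of low-frequency fluctuations (ALFF) summarises the strength
of spontaneous resting-state BOLD activity at a voxel: after demeaning, the
single-sided DFT amplitude spectrum $a(f) = (2/N)\,|X(f)|$ is averaged over
the bins whose frequencies fall in the 0.01–0.08 Hz band,

$$\mathrm{ALFF} = \frac{1}{|B|}\sum_{k \in B} \frac{2}{N}\,|X_k|,
\qquad B = \{k : f_\mathrm{lo} \le k/(N\,\mathrm{TR}) \le f_\mathrm{hi}\}.$$

We use the *mean* rather than the sum of bin amplitudes so that values are
comparable across window lengths; a sinusoid of amplitude $A$ at an exact
in-band bin yields $A/|B|$.  Demeaning only affects the DC bin, which is
never in the band, so windowed and full-length computations use the same
formula.

*Dynamic* ALFF recomputes this quantity inside a sliding window — by
default 50 volumes (100 s at TR 2 s) advancing 1 volume at a time, which
segments a 175-volume run into $\lfloor(175-50)/1\rfloor + 1 = 126$
windows.  Each voxel's windowed values are summarised by their mean,
standard deviation (denominator $n-1$) and coefficient of variation
$\mathrm{CV} = \mathrm{SD}/\mathrm{mean}$.  The CV map is the default input
to group inference because it is invariant to per-subject multiplicative
scaling (scanner gain, global amplitude); the SD map is also produced, and
either can be selected (`pipeline_config(map = )`).  Voxels whose mean
windowed ALFF falls below $10^{-12}$ (background) get CV 0 and are flagged
rather than producing division blow-ups.

The sliding-window stack is computed by demodulated running sums
(`src/kernels.cpp`): for bin $k$ the windowed coefficient is a difference
of prefix sums of $x_t e^{-2\pi i k t/w}$, identical in modulus to the
window-local DFT, making the whole 126-window stack $O(T)$ per bin per
voxel.  Unit tests verify the stack against per-window `fft()` to
$10^{-10}$.

## Temporal preprocessing

The per-run chain is: discard the first 10 volumes (equilibration), spatial
Gaussian smoothing (6 mm FWHM), nuisance regression, ideal Fourier
band-pass (0.01–0.08 Hz).  Choices worth spelling out:

* **Band-pass as an ideal spectral mask.**  Out-of-band DFT coefficients
  (including DC) are zeroed exactly.  This matches the spectral definition
  of ALFF bin-for-bin, is idempotent, and is testable against a direct DFT;
  an IIR filter would only approximate the band edges.
* **Detrending** is a linear-trend column inside the nuisance regression
  (on by default): ALFF convention requires removing slow drifts, and the
  intercept+trend formulation keeps it inside one least-squares projection.
  The nuisance set accepts arbitrary regressors; `friston24()` builds the
  24-parameter motion expansion, and mean white-matter/CSF series can be
  appended.  Collinear columns are dropped with a warning.
* **Smoothing before filtering.**  Both operations are linear, one acts on
  space and the other on time, so they commute exactly; we follow the
  common volume-pipeline order (smooth first).  Smoothing uses a separable
  truncated Gaussian ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$ per axis in
  voxel units, radius $4\sigma$, zero-padded boundaries), so interior mass
  is conserved.
* **Motion quality control.**  Framewise displacement follows the Power
  convention — summed absolute backward differences of the six realignment
  parameters with rotations converted to arc length on a 50 mm sphere —
  because that is the convention under which a "mean FD 0.3" exclusion
  threshold is meaningful.  The subject-level rule excludes on
  \>2 mm translation, \>2° rotation, or mean FD \>0.3 (units: mm).  The
  package does not estimate motion (simulated data carry none); it consumes
  realignment output, so the rule remains testable.

## Group inference

Group comparison is a voxelwise ordinary-least-squares GLM on the
per-subject variability maps with intercept, a 0/1 patient indicator, and
mean-centred age, sex (0/1) and mean-FD covariates; the group t statistic is
$t = c^\top\hat\beta \big/ \sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}$
with $n - p$ degrees of freedom.  With no covariates this is exactly the
pooled two-sample t (tested to $10^{-10}$).  Maps are z-scored within the
mask per subject before the GLM (on by default) to remove inter-subject
scale; the correlation and classification features always use the raw maps.

Cluster-level correction follows random-field theory.  Residual images are
standardised voxelwise and the variance of their spatial first differences
gives a per-axis smoothness estimate
$\mathrm{FWHM} = v\sqrt{4\ln 2/\lambda}$ (floored at the voxel size $v$);
white-noise residuals estimate close to one voxel, 6 mm-smoothed noise
within ~10 % of 6 mm.  With resel count $R = V/\prod(\mathrm{FWHM}/v)$, the
expected number of clusters above the voxel threshold $u = t_{1-p}(\nu)$
uses the 3D Euler-characteristic density of a t field; the extent tail is
the standard stretched-exponential
$P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)/E[n])^{2/3}$, and the corrected cluster p-value is
$1 - \exp(-E[m]\,P(n \ge k))$.  The voxel threshold is two-sided by
default (the analysis reports both signs), and $E[m]$ is doubled
accordingly so the family-wise rate covers both excursion sets.  Lower-
dimensional resel terms are omitted — adequate away from the degenerate
regime (see limitations).  Clusters use 26-connectivity by default
(configurable 6/18), and a label-permutation cluster-extent null
(`permutation_cluster_correction()`) is provided as a nonparametric
cross-check of the parametric formulas.

Regional association with clinical scores uses partial correlation:
Pearson correlation of residuals after projecting out intercept, age and
sex, with $t = r\sqrt{(n-2-k)/(1-r^2)}$ for the two-sided p.  Demographic
tables use the Pearson chi-square without continuity correction for sex and
the same GLM machinery (two-sample t when no covariates) for scalar scores.

## Classification

The classification feature is the subject-mean variability over the
surviving cluster (one number per subject; a voxelwise mode exists).  A
linear soft-margin SVM (libsvm via e1071) at cost $C = 1$ is evaluated by
leave-one-out cross-validation, with a stratified 10-fold alternative;
features are standardised with each training fold's mean/SD only.
Held-out decision scores are pooled for the ROC, whose AUC is the
tie-aware rank statistic.  Significance comes from a label-permutation
test: labels are shuffled (preserving group sizes), the *entire*
cross-validation is re-run per shuffle, and
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$ —
never zero by construction.  A score of exactly 0 is assigned to the
control class.

Two cautions are deliberately visible in the design.  First, selecting the
feature cluster on the full sample and then cross-validating (the
conventional procedure this package reproduces by default) is optimistically
biased; the building blocks (`fit_voxelwise_glm()`,
`grf_cluster_correction()`, `extract_cluster_feature()`) can be re-run
inside each training fold for a nested, unbiased estimate, and the
permutation test — which repeats only the CV, not the selection — should be
read accordingly.  Second, leave-one-out accuracy with balanced classes is
*pessimistically* biased at chance (the held-out subject's class is always
the training minority), which is why the permutation calibration checks use
stratified k-fold.

## The synthetic cohort

Because the package must be testable end-to-end without clinical data, the
generator builds a cohort with the statistical structure the analysis
assumes: two groups of 28 subjects, TR 2 s, 185 volumes (10 discarded
downstream), 3 mm voxels, 0.01–0.08 Hz signal content, 6 mm smoothness.
Every voxel carries an independent Gaussian band-limited carrier built in
the Fourier domain (random-phase complex-Gaussian coefficients at in-band
bins only, unit expected variance, exactly zero mean).  The planted effect
is a slow sinusoidal amplitude modulation
$x_t \cdot (1 + d\sin(2\pi f_m t + \phi))$, $f_m = 0.005$ Hz, applied to
patient voxels inside a radius-2.5 sphere (81 voxels) centred in the
16×16×16 grid.  This mechanism raises the across-window SD of windowed
ALFF roughly by $d/\sqrt2$ in relative terms while leaving mean ALFF
essentially unchanged — matching a phenotype of altered ALFF *dynamics*
without an ALFF *level* difference.  The envelope phase is drawn once per
subject, making the modulation regionally coherent.

Default generator settings, chosen once as realistic study conditions: mean
modulation depth 0.6 in patients; per-subject depth coupled to disease
duration, $d_i = 0.6 + 0.05\,(\mathrm{dur}_i - \overline{\mathrm{dur}})$
floored at 0, with durations $\sim N(8.46, 2.92^2)$ years — the coupling
makes regional variability track duration, qualitatively reproducing a
strong positive duration correlation; white noise of SD 1 (signal-to-noise
1 against the unit-SD carrier), spatially smoothed at 6 mm so the residual
fields have the smoothness random-field inference assumes.  Ages are
$N(59, 8^2)$ in both groups, sex is Bernoulli(1/2), cognitive scores use
the group means/SDs of the emulated cohort (MoCA slightly lower in
patients), and mean FD is a scalar covariate below the exclusion threshold.
All randomness flows from one integer seed: covariates first, then one
derived sub-stream per subject, so cohorts are byte-identical across calls.

What the generator does *not* emulate: hemodynamic response shape, head
motion imagery, physiological noise spectra, anatomical structure, or
MNI-space geometry.  Passing tests therefore demonstrate statistical
correctness of the machinery (calibrated false positives, recovery of a
known effect, reproducibility), not robustness to the artefacts of real
acquisitions.

## Problem sizes and calibration checks

The test suite exercises the full pipeline at the study's cohort size on a
compact grid, as this package's own choice of desk-scale conditions:

* **Null calibration** — 50 depth-0 cohorts (16³ grid, 28+28 subjects):
  the voxelwise two-sided p<0.001 exceedance rate should sit within
  sampling error of 0.001, and the corrected cluster-level false-positive
  rate at cluster p<0.05 should be compatible with ≤0.05.
* **Effect recovery** — 20 cohorts at depth 0.6 and noise SD 1 on a 12³
  grid (same 81-voxel planted sphere): the largest surviving cluster should
  overlap the planted region (Dice > 0.5) and leave-one-out accuracy on the
  cluster-mean feature should exceed the 95th percentile of its own
  200-iteration permutation null, in at least 90 % of seeds.
* **Permutation calibration** — 200 label-shuffled experiments at
  $n_\mathrm{perm} = 99$ (stratified 8-fold, 56 subjects): the permutation
  p-values should be approximately uniform (Kolmogorov–Smirnov).

`scripts/acceptance.R` re-runs the same computations from scratch at sizes
chosen to finish in minutes and writes the resulting numbers as JSON.

## Known limitations

* The GRF extent formulas assume a smooth continuum field and moderate
  degrees of freedom.  At very low df (e.g. 8-subject toy cohorts) with
  smoothness near one voxel, $E[n]$ drops below a voxel and tiny noise
  clusters can receive small parametric p-values; the permutation
  correction is the honest alternative there.  At the package's default
  scale (df ≈ 51, FWHM ≈ 1.3–2 voxels) the empirical false-positive checks
  above apply.
* Band edges are resolved to DFT bins of the actual series length; a band
  edge falling between bins is inclusive within $10^{-12}$ Hz tolerance.
* Slice-timing correction, realignment and MNI normalisation are out of
  scope: inputs are assumed voxel-aligned, and motion enters only through
  the QC rule and the mean-FD covariate.
* Windowed ALFF values at nearby windows share most of their data (step 1
  of length 50), so the 126 windows are far from independent; the SD/CV
  summaries are descriptive statistics of the windowed trajectory, not
  estimators with simple sampling theory.
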