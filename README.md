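# dynalff

Sliding-window **dynamic ALFF** analysis of resting-state fMRI in R.

Resting-state BOLD activity is commonly summarised by the amplitude of
low-frequency fluctuations (ALFF): the mean single-sided DFT amplitude of a
voxel's time series over 0.01–0.08 Hz.  A growing literature asks not just
*how strong* this spontaneous activity is but *how stable* it is over
minutes: ALFF is recomputed inside a sliding temporal window (here 50
volumes advancing by 1, so a 175-volume run yields 126 windows) and each
voxel's windowed values are summarised by their standard deviation and
coefficient of variation (CV = SD/mean).  Elevated CV marks regions whose
spontaneous activity waxes and wanes abnormally — a candidate imaging
marker in movement disorders — even when mean ALFF shows no group
difference.

The package implements the full analysis chain for a two-group
(patients vs. controls) study:

* **Temporal preprocessing** — initial-volume discard, head-motion QC
  (Power framewise displacement; 2 mm / 2° / mean-FD 0.3 exclusion rule),
  nuisance regression (Friston-24 expansion, WM/CSF signals, linear
  detrend), ideal Fourier band-pass, Gaussian spatial smoothing.
* **dALFF maps** — static ALFF plus windowed mean/SD/CV maps, computed by
  an \(O(T)\)-per-bin running-sum kernel (Rcpp) and oracle-tested against
  direct DFTs.
* **Group inference** — voxelwise GLM (group + age, sex, mean FD),
  residual-based smoothness estimation, Gaussian random-field cluster-level
  correction at voxel *p* < 0.001 / cluster *p* < 0.05
  \(p_\mathrm{cluster} = 1 - \exp(-E[m]\,e^{-\beta k^{2/3}})\), with a
  label-permutation cluster-extent alternative; partial correlations of
  regional CV with clinical scores; demographics tests (chi-square,
  two-sample t).
* **Classification** — linear SVM on the cluster-mean CV feature with
  leave-one-out or stratified k-fold cross-validation, ROC/AUC, and a
  label-permutation significance test with the add-one rule
  \(p = (1+\#\{\mathrm{null}\ge\mathrm{obs}\})/(1+n_\mathrm{perm})\).
* **Synthetic cohorts** — a seeded generator producing two groups of 4D
  BOLD-like NIfTI runs with band-limited carriers, a planted sphere of
  elevated dALFF variability in patients (slow amplitude modulation whose
  per-subject depth tracks disease duration), smoothed noise, and a
  matched covariates table — so the whole pipeline is testable end to end
  without clinical data.

## Worked example

```r
library(dynalff)
cohort <- simulate_cohort(sim_config(seed = 11))          # 28 + 28 subjects
rep <- run_pipeline(cohort, pipeline_config(n_perm = 499))
print(rep)
dice_overlap(attr(rep$clusters, "label_map") == 1, cohort$effect_mask)
```

```
== Dynamic ALFF analysis report ==

Subjects: 56; windows per run: 126 (length 50 TR, step 1 TR)

Demographics
  Sex (M/F): patients 14/14, controls 13/15; chi-square p = 0.789
  Age: t = -0.65, p = 0.521
  MoCA: t = -1.69, p = 0.097
  MMSE: t = 0.11, p = 0.916
  Cluster-mean CV: patients 0.230 +/- 0.035, controls 0.142 +/- 0.009, p = 3.9e-18

Group GLM: df = 51, residual FWHM 4.0/4.0/4.0 mm, max |t| = 8.40
Clusters (GRF correction, voxel p < 0.001, cluster p < 0.05):
<cluster_table> 1 surviving cluster(s); |t| threshold 3.258, 1698.5 resels
  size peak_t  x  y  z p_cluster
1   71    8.4 24 21 21         0

Partial correlations with cluster-mean variability (patients; age & sex adjusted)
  duration       r = +0.858, p = 2.14e-08
  updrs_iii      r = +0.088, p = 0.67
  hy_stage       r = -0.352, p = 0.0776
  moca           r = -0.157, p = 0.445
  mmse           r = -0.288, p = 0.153

Classification (linear SVM, cluster-mean feature)
  loocv: accuracy 100.00%, sensitivity 100.00%, specificity 100.00%, AUC 1.000
  permutation test (499 shuffles): p = 0.002
```

Reading this: one cluster of 71 voxels survives correction and overlaps
the planted 81-voxel effect region (Dice 0.93); its peak sits at world
coordinate (24, 21, 21) mm on the synthetic grid.  Patients' cluster-mean
CV (0.230) exceeds controls' (0.142) because the planted amplitude
modulation inflates across-window variability; the modulation depth was
coupled to simulated disease duration, which the partial correlation
recovers (r = +0.86) while unrelated scores stay null.  With an effect
this clean the classifier separates the groups perfectly and the
permutation p is at its floor of 1/(1+499).

The generator and every stage are configurable — `sim_config()` controls
cohort size, grid, effect depth/coupling and noise; `pipeline_config()`
controls band, window, smoothing, thresholds, correction method and CV
scheme.  A thin command-line front end lives at `inst/cli/dalff.R`
(`simulate` / `run` subcommands over NIfTI directories).

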