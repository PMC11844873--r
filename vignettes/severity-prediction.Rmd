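---
title: "Predicting Parkinson's disease severity from resting-state fMRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Parkinson's disease severity from resting-state fMRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In longitudinal Parkinson's disease cohorts, disease severity is scored with
the MDS-UPDRS: the sum of parts Ia (rater-assessed non-motor, `NP1RTOT`), Ib
(patient questionnaire, `NP1PTOT`), II (`NP2TOT`), III (motor examination,
`NP3TOT`) and IV (motor complications, `NP4TOT`). `parksev` implements a
complete pipeline that predicts this total — at the imaging visit and at
one, two and four years after it — from regional resting-state fMRI features
combined with clinical and demographic variables, and that quantifies
whether those predictions beat chance. Because the clinical databases this
kind of study draws on cannot be redistributed, the package pairs the
pipeline with a synthetic-data generator whose ground truth is known
exactly, so every stage is testable end to end.

Part IV is frequently missing in practice; `total_updrs()` treats a missing
`NP4TOT` as zero and treats a missing value in any other part as an error.

## Imaging features

Two voxelwise features are computed from denoised 4D volumes:

**Regional homogeneity (ReHo)** is Kendall's coefficient of concordance
$W$ between a voxel's timeseries and those of its 27-voxel neighbourhood
(face, edge and corner neighbours plus the centre). Each of the $K$ series
is rank-transformed over its $n$ timepoints, $R_t$ is the rank sum at
timepoint $t$, $S = \sum_t (R_t - \bar R)^2$, and

$$W = \frac{12\,S}{K^2 (n^3 - n) - K\,T},$$

where $T$ is the tie-correction term. The default omits $T$
(`midrank_no_correction`), matching classic ReHo implementations; the
corrected denominator is available by flag. Under independent series
$\mathbb{E}[W] = 1/K$, which is the calibration the tests check. At mask
edges the neighbourhood is truncated to in-mask voxels (voxels with fewer
than `min_neighbors = 2` in-mask neighbours are zeroed) so the map's support
equals the mask.

**ALFF / fALFF.** Each voxel series is linearly detrended and band-passed
to 0.01–0.1 Hz. ALFF is the standard deviation of the filtered series;
fALFF divides it by the standard deviation of the unfiltered series. Two
choices are deliberately pinned and exposed as options:

* the default filter is an ideal FFT mask (bins strictly outside the band
  zeroed, edges inclusive, frequencies from $n$ and the repetition time),
  which makes fALFF$^2$ exactly the in-band power fraction of the detrended
  series by Parseval's theorem; a zero-phase order-2 Butterworth is offered
  for sensitivity analysis;
* the fALFF denominator defaults to the *detrended* unfiltered series, so
  the ratio is a pure band-power fraction; the raw series is available as a
  variant.

Participant-level z-scoring standardizes each map over the in-mask voxels
with the population (1/N) standard deviation — a fixed convention that must
be pinned for exact tests; with realistic mask sizes the sample-SD
alternative differs by under one part in a thousand.

## Confounds and quality control

Nuisance signals (the six rigid-body motion parameters, tissue-mean
timeseries, component timeseries) are concatenated into a single matrix and
regressed out of every voxel in one joint least-squares fit; an intercept is
always included, so residuals are mean-zero and exactly orthogonal to every
confound column. The regression is idempotent, which the tests assert.
Rank-deficient designs are reported by column name and resolved by pivoted
QR.

Framewise displacement summarizes head motion as the sum of absolute
volume-to-volume changes of the six parameters with rotations converted to
arc length on a 50 mm sphere. The rotation scale is a genuine convention
choice: the standard arc-length reading multiplies the angle by the radius,
while some descriptions multiply by $2\pi \times 50$. The package defaults
to the radius convention and exposes `rotation_scale = "two_pi_radius"` as a
switch; a 0.01 rad step maps to 0.5 mm or $\pi$ mm respectively.
Participants with mean FD above 0.55 mm are flagged but never removed, and
no volume censoring is performed — motion is handled by regression and
reporting only.

## Parcellation

Regional features are the mean map values per label of an integer atlas.
Custom atlases are built by merging label images in a declared order (for
example, a 100-region cortical parcellation followed by 28 cerebellar and 7
striatal regions, giving labels 1..135); overlapping voxels default to
later-part-overwrites — the merge order puts the refining subcortical
parcels last — with the overwritten voxel count logged so the policy can be
audited. Label images are resampled between grids by nearest source-voxel
centre in world coordinates (affine-aware); exact distance ties resolve to
the lower voxel index, a tie-break the brute-force oracle in the tests
shares. Regions left empty after resampling propagate as missing values and
are median-imputed inside training folds by the modelling layer — never
silently zeroed. Region naming computes each region's world-space (mm)
centroid and looks it up in a reference atlas, falling back to the nearest
labelled reference voxel, ties to the lower label.

## Cohort assembly

A follow-up visit matches Year 1/2/4 when its date lies within 60 days of
baseline + 365/730/1460 days. Among multiple matches the closest to the
target wins; exact ties (and the alternative `earliest` policy) take the
earlier visit, for determinism. Clinical and demographic features — disease
and symptom duration, dominant symptom side, GDS, MoCA,
tremor/rigidity/postural-instability indicators, age, sex, ethnicity, race,
handedness, years of education — are encoded with a documented, overridable
code map (`default_code_map()`); there is no canonical encoding for
race/ethnicity/side, so the shipped map is an explicit, documented
convention. The baseline total is added as a feature when predicting
follow-up outcomes. Feature-set variants drop columns by name (`no_side`,
`no_baseline_score`, `clinical_only`, `imaging_only`), mirroring the D.1–D.4
ablation workflows. The severity threshold for post-hoc classification is
the mean of the four per-time-point median totals.

## Evaluation

Four model families are supported: elastic net (glmnet), linear-kernel SVM
regression (e1071), random forest (randomForest) and gradient boosting
(xgboost). Hyperparameter grids are compact, documented defaults
(`default_grid()`) and fully overridable: elastic net mixes
$\alpha \in \{0.1, 0.5, 0.9\}$ with
$\lambda \in \{0.01, 0.1, 1, 10\}$; SVM cost spans $10^{-2}..10$;
the forest varies the candidate-variables fraction; boosting varies tree
depth at a fixed 60 rounds and learning rate 0.3.

Two nested cross-validation schemes are implemented:

* **per-combination** (the default): each family × parcellation is
  evaluated separately; a 10-fold inner loop on the training participants
  selects the hyperparameters with the lowest mean RMSE, the winner is refit
  on all training participants and predicts the held-out one(s);
* **joint** (the E.1 scheme): the inner loop searches over model ×
  hyperparameters × parcellation jointly and one winner predicts the
  held-out participant. With one model and one parcellation the two schemes
  coincide bitwise, which is tested.

R2 and RMSE are computed on the pooled out-of-fold predictions (per-fold R2
is undefined for a leave-one-out outer loop). Continuous features are
standardized and missing values median-imputed *inside each training fold*;
binary indicators pass through raw. The no-leakage contract — the held-out
participant's target cannot influence its own prediction — is asserted by a
mutation test in both schemes. One master seed fans out deterministically
per fold and stage, so every stochastic result is reproducible.

Chance level is estimated by permuting the targets and rerunning nested
cross-validation (5-fold outer and inner, elastic net as the fixed model)
— 1,000 permutations at full scale; the shipped checks use 100, which is
enough to place the null mean within a few thousandths of zero.
Out-of-sample R2 under permuted labels is non-positive in expectation, and
the observed null means are slightly negative. Workflow comparisons flag
best-R2 differences beyond 0.15 — the margin used for cross-study
comparability — and results that do not beat the null's 95th percentile.

Post-hoc classification thresholds true totals and continuous predictions
at the severity threshold; totals at or above it are the high-severity
positive class (the ≥ convention is pinned here; it is not universal). AUC
uses the continuous predictions against the thresholded truths (a midrank
rank statistic; thresholded predictions would make AUC degenerate).

Feature importance is the signed coefficient for the linear families and
the impurity importance signed by the univariate correlation with the
target for the tree families, computed on each outer fold's refit model;
the per-feature median across folds is reported, sorted by magnitude. Exact
duplicate features under the elastic net share their weight; the tests
assert both are selected, not an exact split.

## The synthetic study

The generator emulates every input the pipeline needs.

* **Volumes.** Each atlas region gets a latent signal built from disjoint
  FFT bins so that a fraction $\varphi$ of its power lies in 0.01–0.1 Hz
  exactly; each voxel is $\sqrt{\rho}\,\times$ latent $+
  \sqrt{1-\rho}\,\times$ white noise, so $\rho$ is the ReHo ground truth
  and $\varphi$ the fALFF ground truth. $\rho = 1$ collapses a region onto
  one series (ReHo $\to$ 1); $\rho = 0$ gives the $1/27$ null.
* **Motion.** Six-column random walks; step SDs (0.06 mm, 0.00095 rad)
  are calibrated so mean FD is about 0.258 mm under the radius convention —
  a realistic cohort-level figure.
* **Cohort.** Baseline totals are a linear model over encoded clinical
  features and the package's own regional z-scored fALFF features plus
  Gaussian noise, clipped to [0, 199] and rounded; follow-up totals are
  $0.9 \times$ baseline + imaging terms + noise. The theoretical R2 is the
  empirical variance decomposition
  $\mathrm{Var}(X\beta) / (\mathrm{Var}(X\beta) + \sigma^2)$, recorded in
  the ground-truth object and verified against a 10,000-draw Monte-Carlo
  resampling estimate. By default the baseline noise is set so the
  theoretical baseline R2 is 0.5 and follow-up noise so the follow-up R2 is
  0.75. Totals are decomposed into part scores by a fixed
  Dirichlet(2, 2, 4, 10, 1) split; when `NP4TOT` is set missing (30% of
  visits by default, to exercise the missing-to-zero rule) its mass folds
  into part III so the totals stay exact. Visit dates get uniform jitter
  within ±45 days, inside the ±60-day matching windows; out-of-window
  visits are constructed explicitly in the tests that need them. Retention
  defaults (51/82, 41/82, 30/82) mirror a real longitudinal attrition
  profile, with nested retained subsets.

Default problem sizes are deliberate desk-scale choices, documented here as
the package's study conditions: 120 baseline participants, a 12³ voxel grid
(2 mm isotropic), 200 timepoints at TR = 2.4 s, and three parcellations —
a primary atlas merged from cortical-like (6), cerebellar-like (4) and
striatal-like (2) parts, plus coarse (6) and fine (24) alternatives —
standing in for the 135/197/444-region atlases a full-scale analysis would
use.

What the generator does *not* emulate: anatomical structure, scanner
artifacts, physiological noise, spatial autocorrelation beyond the regional
latents, and registration error. Passing tests therefore demonstrate that
the algorithms are correct and the evaluation honest — not that the model
families would achieve any particular performance on real data.

## Worked example

```{r, eval = FALSE}
library(parksev)

study <- synth_study(n_baseline = 60, seed = 7)
study$truth$theoretical_r2

report <- run_workflow(study, workflow_config("default",
                                              parcellations = "primary",
                                              timepoints = "Baseline",
                                              seed = 7))
report
report$metrics

fit <- report$best$Baseline$fit
plot(fit)
head(feature_importance(fit))
```

## Numerical choices and limitations

* All-constant timeseries blocks have no defined $W$; they return 0 with a
  `degenerate` flag. Constant in-mask maps make z-scoring an error, and
  constant targets make R2 an error, by design.
* Inner-loop ties on RMSE resolve to the first grid point in declared
  order; distance and centroid ties resolve to the lower index/label.
* fALFF can exceed 1 by a small filter-edge margin; values are reported as
  computed and the property tests bound the excess at 0.05.
* The leave-one-out outer loop gives pooled R2 a known small pessimistic
  bias at moderate n; the recovery check uses the 0.15 comparability margin
  rather than expecting exact equality with the generative R2.
* Preprocessing variants that live upstream of this package (segmentation,
  registration, ICA-based denoising) are represented only through their
  outputs — alternative confound matrices and masks supplied as inputs.
```
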