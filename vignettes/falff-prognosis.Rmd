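---
title: "Predicting aphasia therapy outcomes from resting-state fALFF: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aphasia therapy outcomes from resting-state fALFF: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`falffprog` implements a prognostic pipeline for chronic post-stroke aphasia:
given one resting-state BOLD run per patient and a pre-treatment score on a
bounded treatment-specific measure (TSM), it predicts the post-treatment
score from data-driven imaging features, and compares that imaging model
against one built from a conventional behavioral battery. This vignette
explains the model at each stage, the tunable parameters and their defaults,
the design decisions taken where several readings were defensible, what the
synthetic cohort generator does and does not emulate, and known limitations.

## Quality control: weighted slice-wise temporal SNR

Scans are screened by temporal signal-to-noise ratio before any analysis. For
each axial slice (the third array axis), every in-mask voxel's temporal mean
is divided by its temporal standard deviation (n − 1 denominator) and the
voxel values are averaged over the slice; the scan-level value is the mean
over slices weighted by each slice's brain-voxel count, and a scan passes at
weighted tSNR ≥ 100 (strictly below 100 is excluded).

Two readings of "slice-wise mean signal over standard deviation" are
defensible: per-voxel tSNR averaged within the slice, or pooled slice
statistics. The per-voxel reading is the default because it is standard
practice and robust to within-slice intensity gradients; the pooled variant
(slice mean intensity over the sd of the slice-mean time course) is available
as `method = "pooled"`. Slices with no brain voxels, or with zero temporal
variance, are excluded from the weighted mean with a warning rather than
poisoning the aggregate. When a subject has several runs, `select_best_run()`
keeps the highest-tSNR run, breaking exact ties in favour of the earliest.

## Group ICA: reduction, InfoMax, back-projection, stability

The decomposition is temporal-concatenation group spatial ICA:

1. **Subject reduction.** Each voxel time course is demeaned and the t × t
   temporal covariance eigendecomposed; the subject is represented by its top
   k eigen-directions. The default k is 1.5 × the component count, truncated
   to the subject's numerical rank (voxel demeaning leaves at most t − 1).
2. **Group reduction and whitening.** Reduced subjects are stacked and a
   second PCA retains the requested number of components (default 20, the
   convention for this analysis; synthetic examples typically use the number
   of planted sources), whitened to identity covariance over voxels.
   Requesting more components than the group rank is an error, not a silent
   truncation.
3. **InfoMax unmixing.** Natural-gradient InfoMax with a logistic
   nonlinearity and bias term, full-batch updates, random orthogonal
   initialization from the seed. The learning rate starts at 0.2 and halves
   whenever the update direction reverses; convergence is declared when the
   relative Frobenius update falls below 1e-7, with a 1000-iteration cap and
   a warning (not an error) at the cap. The logistic contrast targets
   super-Gaussian (sparse) spatial sources, which is what compact activity
   patterns look like.
4. **Ordering and sign.** Components are ordered by descending energy in the
   whitened space and each map's sign is fixed so its maximum-magnitude voxel
   is positive, making the decomposition deterministic given the seed.
5. **Back-projection.** Per subject, component time courses are obtained by
   regressing the (voxel-demeaned) data on the group maps, and subject maps
   by regressing the data on those time courses — the dual-regression
   flavour. GICA toolboxes also offer PCA-based back-reconstruction; the
   dual-regression choice is self-contained, well-conditioned and testable,
   and numerical equivalence with any particular toolbox is not claimed.
6. **Stability.** `stability_restarts()` reruns InfoMax from distinct seeds
   (default 100 restarts), greedily matches components across runs by
   absolute spatial correlation, and reports per-component mean
   within-cluster |correlation| — an ICASSO-style quality index in [0, 1].
   Diverging restarts are excluded with a warning; more than half diverging
   is an error.

Cohorts with mixed repetition times are decomposed together; the TR matters
only at the spectral stage.

## fALFF features

For each subject-component time course: linear detrend and demean, unpadded
untapered periodogram, then the ratio of power summed over 0.01–0.08 Hz
(edges inclusive, bins from the length-T transform) to power over all
positive frequencies. The band's upper edge must lie below Nyquist, which
every supported TR (2 and 2.4 s) satisfies comfortably. The ratio is of
*power* (squared magnitude) by default; the amplitude convention
(`mode = "amplitude"`) from the original fALFF literature is available. A
constant series is assigned fALFF 0 with a warning.

Each subject's vector is then standardized to sum to one, expressing relative
component power. Two consequences matter downstream: (i) fALFF is invariant
to amplitude scaling and mean offsets of the time course, so any
variance-normalization a decomposition applies is irrelevant; and (ii) the
standardized features are exactly collinear with an intercept, so individual
regression coefficients are identified only up to a common shift — their
contrasts are the meaningful quantity.

## The prognostic model

Prediction uses elastic-net regression on z-scored predictors, with the
objective

(1/2n) Σᵢ (yᵢ − β₀ − xᵢᵀβ)² + λ (α‖β‖₁ + (1 − α)/2 ‖β‖₂²),

intercept unpenalized. The scaling is stated explicitly because elastic-net
parameterizations differ between implementations; at λ = 0 the fit is OLS
and at α = 0 ridge regression, both of which the tests pin to closed forms.
The solver is cyclic coordinate descent on precomputed second moments with a
compiled inner loop; convergence uses the scaled coordinate-change criterion
(max Δβ² · Gⱼⱼ < 1e-14 by default), which remains well-behaved when p ≥ n.

**Hyperparameter search.** α ∈ {0.1, 0.325, 0.55, 0.775, 1.0} crossed with a
25-point log-spaced λ path from λ_max (the smallest λ zeroing every
coefficient) down four decades — two decades when p ≥ n, where the
unpenalized end of the path is underdetermined (the same convention glmnet's
`lambda.min.ratio` uses). The grid point minimizing LOOCV mean squared error
wins; ties break deterministically toward larger λ, then smaller α.

**Nesting.** Whether hyperparameter selection sits inside or outside the
prediction cross-validation is a genuine design choice at these sample
sizes. The default here is fully nested — standardization parameters,
hyperparameters and coefficients are all recomputed within each outer fold,
so the held-out subject leaks into nothing — because non-nested LOOCV is
optimistically biased. `nested = FALSE` reproduces the cheaper variant for
comparison. Predictions are clamped to the measure's dynamic range
([0, 1] by default), and a final all-rows fit supplies the reported
coefficient vector on the z-scored scale.

**Missing data.** Behavioral cells may be missing; outcomes may not.
`impute_missing()` is iterative random-forest imputation: initialize at
column medians, then repeatedly re-predict each incomplete column from the
others with a 100-tree forest fit on its observed rows, up to 10 sweeps or
stabilization. `ensemble_run()` repeats imputation + LOOCV across seeded
imputations (the full design uses 1000; tests and examples use 10) and
aggregates predictions and coefficients by elementwise median, recording
coefficient min/max across imputations. With no missing cells every
imputation is identical, so a single fit is performed and the ensemble equals
it exactly. An optional sweep (`select_imputation_trees()`) picks the forest
size minimizing imputed-value variance across seeds, the selection criterion
described for this design.

## Assessment harness

* **MAD** — median of |predicted − actual| (midpoint convention at even n).
* **Chance comparison** — one-sided paired Wilcoxon signed-rank on the
  per-subject absolute deviations of the model versus the chance model. The
  chance model predicts the sample mean of the actual scores; a literal
  alternative reading (deviations of the predictions from their own mean) is
  available behind `variant = "predicted_mean"` but is not a chance model,
  so it is not the default.
* **Signed-rank details** — zeros are handled by the Pratt method (rank with
  zeros, then drop), ties by average ranks. For n ≤ 25 the p-value is exact
  under the sign-permutation null, computed by convolving the rank
  generating function (identical to the classical exact distribution when no
  ties or zeros are present, and still exact with them); beyond 25 a normal
  approximation with tie correction and continuity correction is used. Zeros
  arise naturally here because clamped predictions create exact ties.
* **R²** — squared Pearson correlation between predicted and actual, with a
  one-sided test that the correlation exceeds zero (t on n − 2 degrees of
  freedom). Constant vectors report R² = 0 with p = 1 and a warning.
* **Confidence intervals** — no interval construction is canonical for MAD
  or squared correlations at these sample sizes, so the package uses a
  case-resampling percentile bootstrap (2000 replicates, seeded).
  Degenerate replicates (e.g. constant resamples for correlation metrics)
  are skipped; more than 20% of them is an error. In ensemble mode CIs are
  computed on the median-aggregated predictions, matching how ensemble
  predictions are displayed.
* **Treatment effect** — one-sided signed-rank that post-treatment scores
  exceed pre-treatment scores.

## Behavioral multicollinearity

Group sample sizes are imbalanced, so pairwise Kendall tau-b is computed
within each impairment group on pairwise-complete observations (no
imputation; a cell needs at least 3 complete pairs per group or that group
abstains from it) and then averaged cell-wise, unweighted, across groups.
tau-b is the tie-corrected form (C − D)/√((n₀−n₁)(n₀−n₂)); bounded clinical
scores tie frequently, so the correction is not optional.

Clustering uses UPGMA (unweighted average linkage) on correlation distance.
Two distance conventions circulate in this literature — 1 − τ, and 1 − |τ|
when anticorrelated measures should cluster together — and analyses are not
always explicit about which they used. Both are provided
(`absolute = TRUE/FALSE`) with the signed form as default, so either reading
can be reproduced. UPGMA is backed
by `stats::hclust(method = "average")`, whose internal tie handling is
deterministic but not the lexicographic rule one might specify on paper; all
stated properties (monotone merge heights, exact reproduction of ultrametric
inputs in cophenetic distance, leaf-order invariance) hold regardless.
Dendrograms export to Newick with heights as branch lengths.

## The synthetic cohort generator

No patient data ship with the package, so the generator is first-class,
tested code that defines the study conditions every stage is exercised
under:

* **Scans.** Sources are smoothed Gaussian blobs with compact support,
  placed with a minimum centre separation so pairwise spatial |r| < 0.2
  (approximate independence by construction; real components here need not
  resemble canonical language networks, so no anatomical template is used).
  Component time series are synthesized to hit a prescribed fALFF: sums of
  random-phase sinusoids at DFT bins strictly inside 0.01–0.08 Hz and
  strictly above 0.09 Hz are each made to lie jointly in the detrended and
  band-limited subspaces by alternating projections, then amplitude-mixed by
  a monotone bisection until the realized band fraction matches the target
  (within ±0.02 by contract, typically much closer). Scans are the planted
  map × time-series mixing plus white noise (sd 0.1 by default) on a
  baseline intensity of 1000, giving realistic tSNR. The default grid is
  12 × 12 × 8 voxels with 120 volumes at TR 2 s — a desk-scale setting that
  keeps the full suite fast while preserving every qualitative property;
  full 210-volume runs are supported and used for the spectral analytics.
* **Behavioral battery.** 27 bounded scores from a common-factor model (one
  weak general factor loading 0.35 on all measures plus three block factors
  loading 0.7, Gaussian uniqueness, probit-transformed to (0, 1)), giving
  the within-battery multicollinearity the association analysis expects.
  Missingness is injected completely at random at 3.3% — a realistic rate
  for incomplete testing and lost follow-up in multi-site aphasia cohorts,
  with MCAR as the neutral mechanism — on baseline behavioral cells only;
  pre/post outcome columns are never masked, mirroring designs where the
  primary measure is always collected.
* **Outcomes.** post = clamp₀₁(0.5 · pre + Σₖ wₖ xₖ + ε) with pre ~
  U(0.3, 0.9), x the sum-to-one standardized true fALFF, and ε Gaussian
  (sd 0.03 by default). Source weights are alternating-sign contrasts
  (magnitudes 0.8 down to 0.3) shifted by a constant chosen so the expected
  treatment gain is +0.1 — because the features sum to one, the shift is a
  pure intercept and leaves the learnable signal untouched, while making
  post scores exceed pre scores on average as observed clinically. The
  component-wise effect sizes are free parameters of the generator: no
  established component-wise effects linking fALFF to treatment outcome
  exist to calibrate against, so none are claimed.
* **Reproducibility.** One master seed fans out to per-subject, per-component
  sub-seeds through a fixed affine splitting rule, so cohorts are
  bit-identical across runs and stable under subject reordering.

What the generator does **not** emulate: hemodynamic response shapes,
scanner drift and spike artifacts, motion, physiological (cardiac or
respiratory) structure, lesions, or spatial autocorrelation of noise. Tests
passing on these cohorts therefore establish correctness of the algorithms
under their stated models — planted-source recovery, spectral fidelity,
leakage-free cross-validation — not performance on real patient data, where
preprocessing and physiological confounds dominate.

## Numerical choices, at a glance

| Choice | Value | Note |
|---|---|---|
| tSNR definition | per-voxel, slice-averaged | pooled variant available |
| tSNR threshold | pass iff ≥ 100 | exclusion is strictly-below |
| Temporal sd | n − 1 denominator | everywhere |
| fALFF band | [0.01, 0.08] Hz inclusive | unpadded, no taper, linear detrend |
| fALFF ratio | power (squared magnitude) | amplitude variant available |
| InfoMax | logistic + bias, lr 0.2 halving, tol 1e-7, 1000 iters | seeded orthogonal init |
| Subject PCA dimension | 1.5 × components | truncated to rank |
| Elastic-net objective | (1/2n) RSS + λ(α‖β‖₁ + (1−α)/2‖β‖₂²) | intercept unpenalized |
| CD convergence | max Δβ²·Gⱼⱼ < 1e-14 | compiled inner loop |
| λ path | 25 points, 4 decades (2 when p ≥ n) | per-α λ_max |
| Tuning tie-break | larger λ, then smaller α | deterministic |
| Imputation | 100 trees, ≤ 10 sweeps, rel. tol 1e-4 | seeded |
| Signed-rank | Pratt zeros, average ranks, exact ≤ 25 | generating-function DP |
| Bootstrap | percentile, 2000 replicates | degenerate resamples skipped |
| UPGMA ties | hclust internal | heights monotone regardless |

## Limitations

The models are linear with heavy regularization by design; no interaction
between baseline severity and other predictors can be expressed. Change
scores (post − pre) are deliberately not modeled: bounded measures impose
ceiling effects that make gain scores misleading for high-baseline subjects.
Coefficients on sum-to-one features are identified only up to a common
shift, and under multicollinearity ridge-style shrinkage spreads magnitude
across correlated predictors, so individual coefficients should be read as
contrasts within a regularization path, not causal effects. The group ICA
is a faithful but independent implementation: no claim of numerical
equivalence with GIFT or any other toolbox is made, and the back-projection
is the dual-regression flavour. Finally, the synthetic validation regime is
exactly that — synthetic; the generator's scope (above) bounds what the
green tests demonstrate.
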