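---
title: "Brain entropy from BOLD signals: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain entropy from BOLD signals: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintropy)
```

## The problem

Resting-state fMRI measures blood-oxygen-level-dependent (BOLD) signals, an
indirect proxy of neural activity. The temporal *complexity* of these
signals — how irregular, hence how information-rich, the fluctuations are —
declines with aging and neurodegeneration. braintropy quantifies that
complexity voxel by voxel with **amplitude-aware permutation entropy
(AAPE)**, averages it over atlas regions of interest (ROIs), and provides
the two statistical analyses such a regional entropy profile feeds in
practice: a two-group comparison under false-discovery-rate control, and
prediction of neuropsychological scores from regional entropy using a
cross-validation-tuned linear-kernel ridge regressor. The scientific use
case the defaults mirror is the comparison of subjective cognitive decline
(SCD) against normal aging (NA), two groups of 43 subjects with 197-volume
acquisitions at TR = 3 s.

## Amplitude-aware permutation entropy

For a series $X = \{x_1,\dots,x_N\}$ and embedding dimension $m$, every
window $X_m(i) = \{x_i,\dots,x_{i+m-1}\}$ is assigned the permutation
$\pi$ of its time offsets that sorts the samples ascending — its *ordinal
pattern*, one of $m!$ possibilities. Classic permutation entropy is the
Shannon entropy of the pattern relative frequencies; it discards all
amplitude information. AAPE instead lets each window vote with the weight

$$w_i \;=\; K\cdot AA_i \;+\; (1-K)\cdot RA_i,
\qquad
AA_i = \tfrac1m \sum_{l=1}^{m} |x_{i+l-1}|,
\qquad
RA_i = \tfrac1{m-1} \sum_{l=2}^{m} |x_{i+l-1}-x_{i+l-2}|,$$

i.e. a mix of mean absolute amplitude and mean absolute successive
difference, and the entropy is taken over the weight-normalized pattern
distribution $p(\pi_k)$ with the convention $0\ln 0 = 0$:

$$\mathrm{AAPE}(m) = -\sum_{k=1}^{m!} p(\pi_k)\,\ln p(\pi_k).$$

Values live in $[0, \ln m!]$, in nats; 0 means one pattern carries all
weight (a monotone series), and long i.i.d. noise approaches $\ln m!$.
Because the weights are homogeneous of degree one, AAPE is exactly
invariant to positive rescaling of the series.

### Numerical conventions

* **Magnitudes in the weights.** Printed formulations of the amplitude
  terms sometimes omit the absolute-value bars; without them window
  weights can be negative and the "probabilities" invalid. We use
  magnitudes throughout, the convention of the original AAPE proposal.
* **Ties.** Equal amplitudes are ordered by time offset (stable ascending
  sort), consistent with the defining inequality chain allowing equality.
  Patterns are reported as 0-based offset strings, e.g. `"2013"`.
* **Degenerate input.** An identically-zero series has total weight zero;
  the pattern distribution is then defined as a point mass (entropy 0)
  and flagged with a warning rather than returning NaN.
* **Parameters.** Defaults are $m = 4$ (24 patterns) and $K = 0.5$ (equal
  emphasis), the values appropriate for 190-sample BOLD series: the
  recommended length condition $N > 5\,m!$ gives $190 > 120$. The
  constructor warns, but does not fail, outside $m \in [3,7]$ or below
  that length, since short-series behavior is sometimes exactly what one
  wants to study. Entropy is reported raw (nats); `normalized = TRUE`
  divides by $\ln m!$.
* **Implementation.** The voxelwise kernel is C++ (one pass per series,
  stable insertion ranks, weight accumulation per pattern code); the test
  suite verifies exact (1e-12) agreement with an independent, deliberately
  naive R transcription of the definition on random short series.

## The imaging pipeline

`subject_profile()` chains the three steps applied to each subject:

1. **Volume discard** — the first 7 of 197 volumes are dropped
   (T1-equilibration guard), leaving 190 for analysis.
2. **Voxelwise AAPE** — computed for every voxel with a positive atlas
   label and nonzero temporal variance. Zero-variance voxels carry no
   dynamics; they are marked invalid rather than entering as entropy 0,
   which would bias regional means downward.
3. **Regional averaging** — the arithmetic mean of valid voxel AAPE
   values per ROI, with the valid-voxel count reported. An ROI with no
   valid voxel is reported as missing, never silently dropped.

Upstream preprocessing (slice timing, motion correction, nuisance
regression, normalization, smoothing) is out of scope: the pipeline
ingests preprocessed-like images. Optional polynomial detrending
(`detrend_series`) is available but off by default, since the intended
input signal is already nuisance-regressed. Grids must match exactly;
there is no resampling or world-space handling. A minimal NIfTI-1
reader/writer is included because no R NIfTI package is assumed; it
covers single-file `.nii`/`.nii.gz`, the common datatypes, both
endiannesses and slope/intercept scaling, and is cross-validated against
nibabel in the test suite.

## Group statistics

Per ROI, a two-tailed pooled-variance Student t-test compares the group
means; Benjamini–Hochberg step-up adjustment across the ROI family
controls FDR, with significance declared at adjusted $p < q$, default
$q = 0.01$. Two conventions were fixed by recomputing a published
demographics table from its printed summaries:

* **Pooled variance, not Welch** — both reproduce the printed delayed-
  word-recall p-value (~0.020) at these group sizes; pooled is the
  conventional default of the era's neuroimaging stacks and is what
  `ttest_from_summary()` implements from sufficient statistics.
* **No Yates continuity correction** in the 2×2 chi-square — the
  uncorrected Pearson statistic reproduces the printed sex-table p-value
  0.5005 exactly; the corrected one gives 0.65. The printed value forces
  the choice.

ROIs missing in any subject are excluded from the family *before*
adjustment and listed in the output attributes, so the multiplicity count
is always explicit. The group test is unadjusted for covariates, following
the source analysis.

## Entropy-to-score prediction

For each (ROI, measure) pair within one group, the ROI's mean AAPE is
first residualized (OLS, with intercept) on age, sex, education, mean
framewise displacement, ADAS13, ADAS-Word and GDS. A least-squares
linear-kernel regressor with bias — kernel ridge with a linear kernel,
the primal form of a linear LS-SVM — maps residualized entropy to the
measure. The regularization parameter is tuned by 10-fold cross-validated
MSE over a 13-point log-spaced grid, $10^{-3}$ to $10^{3}$.

### Why predictions come from the refit model

Two prediction modes exist, and the distinction matters:

* `"refit"` (default): cross-validation tunes the penalty; the tuned model
  is refit on all subjects and its fitted values are correlated with the
  observed scores. With a linear kernel this correlation equals
  $|\mathrm{cor}(x,y)|$, is always non-negative, and its two-tailed
  t-based p-value is uniform under the null — so Bonferroni-thresholded
  flags have their nominal false-positive rate.
* `"out_of_fold"`: double cross-validation with strictly out-of-fold
  predictions. This is the honest estimate of out-of-sample error, but
  the *pooled correlation* between out-of-fold predictions and truth is
  severely negatively biased under the null (about $-0.35$ at $n=43$,
  $k=10$): each fold's intercept is its training mean, which
  anti-tracks the held-out fold mean. Feeding that correlation to a
  t-test calibrated around zero produces floods of spurious "significant"
  negative correlations.

We verified that the emulated analysis's printed correlation table
behaves like the refit mode (all-positive small correlations for null
pairs; p-values exactly the t-transform of r at $n=43$), so the battery
defaults to it. The out-of-fold mode is retained for error estimation,
with the documented caveat; its fold bookkeeping (no subject's row in its
own training set) is tested.

Significance in the battery uses the Bonferroni threshold
$\alpha / (\#\text{ROIs} \times \#\text{measures})$ — with 8 ROIs and 4
measures, $0.05/32 = 0.0015625$ — applied as a threshold on raw p-values,
not as p-value inflation.

## The synthetic cohort: what it emulates, and what it does not

Access-controlled clinical data cannot ship with a package, so
`generate_cohort()` builds a cohort with the statistical structure the
analysis assumes: two groups of 43; a 12×12×12 grid carrying 20 cubic
3×3×3 ROIs (27 voxels each); 197 volumes at TR = 3 s; lower signal
complexity in 4 designated ROIs of group 2; covariates drawn from the
published group demographics; and one measure (CDRSB) linked to one ROI's
entropy. Each voxel follows a MIX-style regularity model

$$x_t = (1-\lambda)\,\sin(2\pi f\,t\,\mathrm{TR} + \varphi_v)
      + \lambda\,\varepsilon_t,$$

with $f = 0.05$ Hz (inside the typical BOLD band), a random phase per
voxel, and i.i.d. standard normal noise (an AR(1) option exists). AAPE
increases monotonically in $\lambda$. This model was chosen over a pure
AR(1) family because it spans a wide, monotone entropy range at
$N = 190$, $m = 4$.

### Calibration of the regularity scale

The $\lambda \to$ AAPE map was characterized once (300 voxels per point,
$N=190$, $m=4$, $K=0.5$): entropy rises from 2.135 (pure sinusoid)
through a steep, nearly linear region and saturates at ~3.11 for
$\lambda \gtrsim 0.6$ ($\ln 24 = 3.178$ is approached only as
$N \to \infty$). The generator operates at $\lambda_{\text{base}} = 0.30$,
in the steep region, where the local slope is $g' \approx 2.9$ nats per
unit $\lambda$ and the voxel-level AAPE noise is
$\sigma_{\text{vox}} \approx 0.073$. Between-subject variation is
injected as $\lambda$ jitter with $\sigma_\lambda = 0.05$, and the group
shift realizing a target standardized effect $d$ on regional mean AAPE is

$$\Delta\lambda = \frac{d}{g'}\sqrt{(g'\sigma_\lambda)^2 +
\sigma_{\text{vox}}^2 / V},$$

with $V = 27$ voxels per ROI — about 0.06 for the default $d = 1.2$.
Mild convexity of the map inflates the realized subject-level $d$
somewhat (measured 1.1–1.7 across ROIs and seeds); the direction and
order of the effect are as stated, and recovery tests use the realized
world, not the nominal number.

### Score linkage

The linked measure is generated as
$y = r\,z + \sqrt{1-r^2}\,\varepsilon$, where $z$ is the standardized
*covariate-residualized* measured entropy of the linked ROI in group 2 —
measured, i.e. computed by the same pipeline the analysis runs, so the
generating correlation ($r = 0.6$ by default) holds exactly on the scale
the battery analyzes. Measures are deliberately *not* clamped to clinical
ranges: with the published CDRSB moments a floor at zero would truncate a
third of the distribution and silently attenuate the generating
correlation, breaking the linear-Gaussian contract that makes recovery
tests interpretable. PACC component columns are z-scored across the
cohort, mirroring how composite components are standardized.

### What a green test does not establish

The generator emulates *statistical* structure only: no hemodynamics, no
head motion, no scanner noise spectrum, no anatomy-shaped parcels, no
spatial autocorrelation between voxels beyond the shared regional
$\lambda$. Passing recovery tests therefore establishes that the
pipeline detects the kind of regularity differences and entropy–score
links it claims to detect, at the stated sizes — not that any specific
clinical finding would replicate.

## Reproducibility mechanics

Every stochastic entry point takes a seed and uses a private RNG state
(the caller's stream is untouched). `generate_cohort(config, seed)` is
bit-reproducible; `write_cohort()` emits a JSON manifest (seed, full
configuration, per-file MD5) from which the cohort can be regenerated and
verified. The CLI (`simulate` / `entropy` / `analyze` / `all`) reads a
flat JSON config, rejects unknown keys, lets flags override file values,
and writes a per-stage manifest with the package version into the output
directory.

## Known limitations

* The NIfTI reader handles the subset of NIfTI-1 the pipeline needs; it
  ignores orientation (qform/sform) entirely, so inputs must share a
  voxel grid by construction.
* The group comparison is unadjusted for covariates by design; if groups
  are demographically imbalanced, regional differences conflate with
  demographics.
* The refit-mode prediction correlation is an in-sample quantity with a
  calibrated null — it is a detection statistic for an entropy–score
  association, not an estimate of out-of-sample predictive accuracy. Use
  `prediction = "out_of_fold"` (and its MSE, not its pooled r) for the
  latter.
* At $m = 3$ only 6 ordinal patterns exist, which compresses group
  differences; the CLI warns when it is selected.
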