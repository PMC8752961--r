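---
title: "Tissue-weighted ROI means: model, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-weighted ROI means: model, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twroi)
```

## The problem

Multi-compartment diffusion-MRI models decompose each voxel's signal
into a free-water (CSF) compartment and a tissue compartment, and report
tissue metrics — NODDI's neurite density index (NDI) and orientation
dispersion index (ODI), both unitless in [0, 1] — as properties of the
tissue portion only, together with the tissue volume fraction
TF = 1 − FWF. A voxel that is 40% CSF still reports the NDI of its 60%
tissue; the TF records the 60%.

An ROI summary should therefore answer: *what is the mean metric over
the region's tissue?* The conventional arithmetic mean over voxels
answers a different question — the mean over voxels, each counted once
regardless of how much tissue it contains. The two coincide only when
the metric and the tissue fraction are uncorrelated across the ROI.

## Estimators

For metric values $m_i$ and tissue fractions $t_i$ over the $N$ voxels
of an ROI, the package computes:

- conventional mean $\bar m = \frac1N \sum_i m_i$;
- tissue-weighted mean
  $\bar m_t = \frac{\sum_i t_i m_i}{\sum_i t_i} = \frac{\overline{tm}}{\bar t}$,
  where the second ("ratio") form divides numerator and denominator by
  $N$ — it is the form that maps onto voxelwise image arithmetic
  followed by two ordinary ROI means, and both forms are available via
  `tissue_weighted_mean(..., form =)`;
- the population covariance
  $\mathrm{Cov}(m,t) = \frac1N\sum_i (m_i-\bar m)(t_i-\bar t)$
  (denominator $N$, not $N-1$);
- the bias decomposition
  $\bar m - \bar m_t = -\mathrm{Cov}(m,t)/\bar t$.

Using the population covariance makes the decomposition an algebraic
identity for finite samples, not an approximation: expanding
$\overline{tm} = \bar t\,\bar m + \mathrm{Cov}(m,t)$ and dividing by
$\bar t$ gives the bias exactly. Consequences the package's tests
verify: the bias is positive under negative metric–TF correlation and
vice versa; it vanishes when $t$ is constant; and for a fixed covariance
its magnitude scales with $1/\bar t$, i.e. with the degree of CSF
contamination. The ROI median is also provided
(`roi_median()`, midpoint convention for even $N$) since it shares the
conventional mean's equal-voxel weighting and hence its susceptibility
to partial-volume bias.

### Degenerate inputs and numerical choices

- Non-finite metric or TF voxels (failed fits, masked voxels) are
  removed when the `roi_sample` is built, identically for every
  statistic, so the identity above stays exact on the retained voxels.
- TF values outside [0, 1] from imperfect fits are clipped to the unit
  interval with a warning (`clip_tf = TRUE`, the default) or rejected
  (`clip_tf = FALSE`). In `tf_from_fwf()` the tolerance is ±0.01:
  values further out indicate the input is not a volume-fraction map
  at all, and error.
- $\sum_i t_i = 0$ (an all-CSF ROI) is a hard error rather than a NaN:
  the region has no tissue whose mean could be estimated.
- $N = 1$: the population covariance is 0 by definition, so both means
  coincide and the bias is 0 — consistent with the identity.
- Grid validation compares image dimensions exactly and affine entries
  to 1e-4 absolute, loose enough for round-trip float error and tight
  enough to catch a mis-registered or resampled input.

## The group-analysis workflow

On a long-format cohort table (one row per subject × ROI × metric) the
package runs, per metric: Welch two-sample t-tests on per-subject mean
TF per ROI; two-tailed one-sample t-tests of the per-subject bias
against zero within each group and Welch tests between groups; Pearson
correlation across ROIs between the group-mean |bias| and the group
mean of 1/meanTF (one point per ROI, using between-subject means, which
matches a "mean magnitude of bias" summary rather than pooling
subject-level points); a Welch test of per-ROI group-mean |bias| split
by the periventricular flag; and Cohen's $d_s$
(pooled, Bessel-corrected SD; no small-sample correction) computed from
both estimators with Welch significance per estimator.

Choices that were genuinely open:

- **Bonferroni family.** The family is the set of ROIs within one
  metric × test combination (48 for the packaged atlas), not pooled
  across metrics; family size and α are recorded in the run metadata.
- **Contrast direction.** Configurable "reference minus comparison",
  defaulting to the groups' order of appearance (the CLI takes
  `--contrast ref,cmp`).
- **Periventricular test.** One observation per ROI row of the
  definition table — bilateral regions contribute their left and right
  rows separately — and the decision is at uncorrected α, since it is a
  single test per metric × group rather than a per-ROI family.
- **Degenerate data.** Zero variance in both groups with equal means is
  reported as t = 0, p = 1; zero variance with unequal means is an
  error. These conventions keep null simulations well defined without
  hiding genuinely broken inputs.

Standard machinery (t-tests, Bonferroni adjustment, Pearson
correlation) is delegated to R's stats package; the test suite checks
all of it against independent hand-coded formulas, and checks its
calibration (type-I error, family-wise error over 48 ROIs) by null
simulation.

## What the synthetic data emulate

Two generators make every claim testable without any imaging data.

**Fine-grid phantoms** (`fine_grid_phantom()`, `downsample_phantom()`)
represent anatomy below voxel resolution: each fine-grid element is
either CSF or tissue with a local neurite density. Block-averaging to
the "imaging" grid produces exactly what a multi-compartment fit would
ideally report — per voxel, the mean density of its tissue
sub-elements and the fraction of tissue — plus the exact mean density
over all tissue in the region. The defining correctness property,
verified to 1e-12, is that the tissue-weighted mean of the downsampled
voxels equals that fine-grid tissue mean identically (the sums
reorganise exactly), while the conventional mean deviates whenever TF
varies and correlates with the metric, with the deviation's sign
opposite to the covariance's.

**ROI and cohort simulation** (`simulate_roi_sample()`,
`simulate_cohort()`). Voxelwise TFs are drawn from a Beta distribution
parameterised by mean and spread — chosen for its bounded (0, 1)
support, since no generative model for empirical TF distributions is
established — and the metric depends on TF linearly,
$m_i = \mu + \kappa\,(t_i - \bar t) + \varepsilon_i$ with Gaussian
noise, truncated to [0, 1] (a warning fires if more than 5% of voxels
clip, since truncation then distorts the recorded ground truth). The
linear link makes the induced covariance analytic
($\mathrm{Cov} = \kappa \mathrm{Var}(t)$ on the noiseless component),
so the predicted bias $-\kappa\,\mathrm{Var}(t)/\bar t$ is exact, and
the ground-truth tissue mean is recorded at generation time.

The default cohort configuration mirrors a case-control study of
neurodegeneration: 21 vs 30 subjects, 48 regions with the packaged
periventricular classification, two metrics sharing each subject's TF
field. Patients have lower TF (atrophy; −0.05 in periventricular
regions, −0.015 elsewhere), periventricular regions have lower TF
(−0.12) and wider TF spread (0.12 vs 0.06), and the metric–TF slope is
more negative in patients and for ODI — producing positive ODI bias
concentrated in periventricular regions and larger in patients, the
regime in which conventional-mean effect sizes are distorted. Metric
levels (NDI ≈ 0.55–0.60, ODI ≈ 0.42–0.45, voxel noise SD 0.05,
between-subject SD 0.02) sit in the range typical of white matter.
Per-region voxel counts are log-spaced over 100–600 on a 24³ grid:
large enough to exercise small-structure/large-structure asymmetry,
small enough that a full 51-subject cohort simulates in seconds. These
sizes, like the validation problem sizes below, are the package's own
choices for a suite that a developer re-runs constantly.

What the generator does **not** emulate — and so what passing tests do
not establish about real data: diffusion-weighted signal formation and
model-fitting noise (fit errors here are i.i.d. Gaussian on the metric,
real NODDI errors are heteroscedastic and correlated with TF itself);
registration and interpolation effects of atlas propagation or
template-space warping; spatial autocorrelation within regions; and
non-linear metric–TF relationships. The phantom covers the geometric
partial-volume mechanism exactly, but with idealised per-voxel
estimates.

## Validation problem sizes

The identity and formulation checks run over 10,000 random samples
(deviations bounded at 1e-12 and 1e-14 relative); phantom exactness
over random 16×16×8 phantoms with 10–40% CSF and a 100-case sign-rule
battery; the bias ∝ 1/TF sweep uses 16 TF levels in [0.5, 0.95] × 20
replicate ROIs of 800 voxels; effect-size distortion uses the
21-vs-30 cohort with patient-only κ = −0.5; calibration uses 1000 null
replicates for the type-I error and 1000 replicate 48-ROI families for
the family-wise error. `scripts/acceptance.R` recomputes all of these
from a single command-line seed.

## Limitations

- The method corrects the ROI *summary*, not voxel values: it estimates
  the mean metric over the region's tissue, and does not attempt
  per-voxel partial-volume correction.
- It inherits the accuracy of the TF estimate itself; systematic FWF
  mis-estimation propagates into the weights.
- Label images must already be on the metric grid; no registration,
  resampling or masking is performed, and affine agreement is only
  checked, not corrected.
- The bias decomposition is exact for the sample at hand; inference
  about a population of subjects still relies on the usual t-test
  assumptions, which the simulated cohorts satisfy by construction but
  real cohorts need not.
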