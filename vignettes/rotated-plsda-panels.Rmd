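---
title: "Rotated PLS-DA for multiplexed immune signaling panels"
author: "plexsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotated PLS-DA for multiplexed immune signaling panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexsig)
```

# Scope

`plexsig` analyzes multiplexed bead-panel measurements — tens of
cytokines/chemokines or phosphoproteins quantified per animal — for
small-cohort stimulation studies. This vignette documents the model, the
assumptions, the numerical choices, and the rationale for every default.
It is a methods document; see the README for a quick worked example.

# Data model and container

A panel is a samples × analytes matrix of strictly positive
concentrations (or bead intensities), with per-sample metadata
(stimulation `group`, exposure `duration`, assay `batch`) and per-analyte
metadata (signaling `panel`/pathway, `in_linear_range`). The
`PanelExperiment` class extends `SummarizedExperiment`, storing the assay
in the Bioconductor orientation (analytes × rows) while `panelMatrix()`
returns the analysis orientation (samples × rows). A `zscored` metadata
flag records whether values are standardized; validity checks enforce
positivity for raw panels and finiteness throughout.

# Preprocessing chain

`preprocessPanel()` applies, in a fixed order:

1. **Linear-range exclusion.** Bead fluorescence is proportional to
   concentration only within the assay's linear range; analytes flagged
   `in_linear_range = FALSE` are removed before any analysis. In the
   bundled phosphoprotein roster 5 of 16 analytes are flagged out,
   leaving 11 usable (4 NF-κB, 7 MAPK).
2. **Z-scoring** per analyte (mean 0, unit sample SD, n − 1
   denominator). This equalizes the influence of analytes whose raw
   ranges span orders of magnitude. Constant analytes raise an error by
   name rather than silently producing NaNs.
3. **Design-aware batch correction** (skipped with a message when only
   one batch is present). Per analyte, a least-squares model with group
   and batch as additive factors (sum-to-zero batch contrasts) is fitted
   and only the fitted batch component subtracted. Keeping the group
   term in the model preserves group-mean differences even under
   unbalanced batch/group layouts, unlike per-batch centering. Batch
   confounded with group is refused as unidentifiable. The result is
   re-z-scored.
4. **Iterative outlier removal.** Each iteration z-scores the remaining
   samples, computes PCA, and measures each sample's squared Mahalanobis
   distance in the leading `nComponents = 2` principal-component scores;
   samples beyond the `confidence = 0.995` ellipse are removed and the
   loop repeats until no sample is outside. The default cutoff is the
   asymptotic chi-square quantile (df = number of components);
   `method = "beta"` substitutes the exact small-sample beta quantile
   for internally studentized distances, which is slightly tighter at
   these n. The loop aborts if fewer than `nComponents + 2` samples
   would remain. A final re-z-score leaves the panel satisfying the
   z-scored precondition of the model fit.

The order matters: exclusion must precede z-scoring (out-of-range values
would distort analyte scales), batch correction operates on comparable
scales (hence after z-scoring), and each removal step changes means and
SDs, so a re-z-score follows every stage that alters the sample set.

# PLS-DA core

Group membership is one-hot encoded as `Y`; NIPALS extracts components
sequentially. Per component the weight vector is the dominant eigenvector
of `(X'Y)(Y'X)`, found by power iteration on the small analytes ×
groups matrix; the score is `t = Xw`; `X` and `Y` are deflated by the
rank-one regression on `t`. Weights are orthonormal across components and
scores orthogonal, which the `PlsdaModel` validity method enforces.

Two numerical choices deserve note:

- **Convergence criterion.** Pure iterate-change criteria stall when the
  top two eigenvalues nearly tie (common under label permutations). The
  iteration therefore stops when either the iterate change or the
  eigen-residual `‖Aw − λw‖/λ` falls below `tol = 1e-10`: in a near-tie
  any vector of the dominant subspace is a dominant direction and the
  residual detects that directly. The iteration cap is generous
  (`maxIter = 50000`) because each step is a tiny matrix–vector product.
- **Sign convention.** The PLS sign indeterminacy is resolved by flipping
  each component so its largest-magnitude loading is positive, making
  fits deterministic for fixed input.

## Rotation of the LV1–LV2 plane

The LV1–LV2 plane is well identified but its basis is not meaningful, so
`rotateLvPlane()` rotates the pair by the angle maximizing the
between/within mean-square ratio (an F-like statistic) of the rotated-LV1
scores under a *contrast*: `"all"` (multi-group) or one group versus the
pooled rest. The angle is found by a grid search over [0, π) at 0.5°
steps — the objective can be computed for all grid angles at once as a
single matrix product — followed by golden-section refinement
(`stats::optimize`) around the best grid point. Rotation is applied
jointly to loadings and scores, preserving loading orthonormality and the
score variance captured by the plane; the sign convention is re-applied
per rotated component. Perfect separation (zero within-group variance)
is reported as `Inf` with a `capped` flag rather than an arbitrary large
number.

# Resampling inference

Because the rotation *optimizes* group separation, naive F tests on the
rotated scores are anti-conservative. Both inference tools therefore
re-run the full fit-plus-rotation per resample:

- `permutationTest()` shuffles group labels (optionally within batches),
  recomputes the rotated-LV1 separation per shuffle, and reports
  `p = (1 + #{null ≥ observed}) / (B + 1)` — the add-one rule never
  returns 0 and makes the minimum attainable p explicit. `B ≥ 100` is
  enforced.
- `looLoadingStability()` cycles deterministically through the samples,
  excluding one at a time (each sample `floor(nRefits/n)` or
  `ceiling(nRefits/n)` times), re-z-scores, refits, rotates, and
  sign-aligns each refit's LV1 to the full-data LV1 by the sign of their
  dot product — the rotated axis has no intrinsic sign, so alignment is
  what makes averaging meaningful. The per-analyte mean and SD over
  refits form the error-bar envelope for loading plots. Samples whose
  exclusion would leave a group with fewer than 2 members are skipped
  with a warning. Since refits are deterministic per excluded sample,
  unique refits are computed once and weighted by their schedule counts.

# Univariate follow-up

- `oneWayAnova()` wraps the classical equal-variance decomposition, with
  degenerate inputs (zero within-group variance) reported at the numeric
  floor with a flag instead of erroring.
- `dunnettTest()` compares every group to a reference. The joint null of
  the comparison statistics is a correlated multivariate t with the
  exact one-factor structure `ρ_ij = λ_i λ_j`,
  `λ_i = √(n_i/(n_i+n_0))`; the adjusted p is the tail of the maximum
  absolute component, evaluated by seeded Monte Carlo (shared chi-square
  denominator, one common factor), with the MC standard error reported
  so users can judge the precision. Adjusted p-values are clamped to be
  ≥ raw p (mathematically true of the exact quantity). At k = 2 the
  procedure reduces to the two-sided t test; the implementation accepts
  k ≥ 2 so that limit is reachable.
- `tukeyHsd()` uses the studentized range (`stats::ptukey`,
  Tukey–Kramer form for unbalanced sizes). At k = 2,
  `q = √2·|t|` makes the adjusted p equal the raw two-sided t p.
- `foldChangeCompare()` divides both arms by the control's per-analyte
  mean, t-tests each analyte on the fold-change scale, and adjusts the
  family by the Holm–Šidák step-down (`1 − (1 − p_(i))^(m − i + 1)`,
  monotone-enforced), which is implemented directly because
  `stats::p.adjust` offers Holm–Bonferroni but not Holm–Šidák.

# Correlation networks

`correlationNetwork()` takes one condition subset (group × duration),
drops out-of-range analytes, computes all pairwise Pearson correlations,
two-sided p-values via the t transform with n − 2 df, and BH q-values
over the full pair family; edges with `q < 0.1` are retained and classed
within-/between-pathway. Constant analytes are dropped from the family
with a warning (their correlations are undefined). At least 4 samples
are required — below that the t transform has no degrees of freedom to
speak of.

# Synthetic panels with ground truth

`generatePanel()` draws log-normal measurements:

```
log x = baseline + group shift + batch offset + Σ block-loading · factor + noise
```

with per-analyte baselines `N(2, 0.5)`, planted group shifts and batch
offsets (fixed or drawn `N(0, batchSd)`), latent-factor blocks inducing
within-block correlation `λ²/(λ² + σ²)` on the log scale, i.i.d. noise,
and whole-sample outliers (a fixed count `round(fraction · n)`, shifted
on every analyte by `outlierMagnitude · noiseSd`). Batches are assigned
round-robin within each group × duration cell so batch is never
confounded with group. Everything is governed by the design seed, and
the returned `PanelGroundTruth` records the planted discriminating
analytes, correlated pairs, outlier samples, and effect matrices.

Default `noiseSd = 0.3` corresponds to ~30% coefficient of variation,
typical of between-animal variability in tissue bead panels; it is a
realism choice, not a tuning knob. The fold-change validation fixture
uses `sd = 0.15` instead: a power analysis at n = 6 shows a 1.5-fold
effect needs raw p ≈ 0.01 to survive Holm–Šidák in a small family, which
30% CV cannot deliver reliably — the fixture is designed (a priori) to
test the *contrast machinery*, not the power limit of n = 6.

`emulateStudyDesigns()` provides two canned shapes: a cytokine study
(4 stimulation groups × 6 animals, 32 analytes, single batch) and a
phosphoprotein study (40 Hz vs random flicker at 3 exposure durations
with unbalanced 40 Hz cohorts of 17/12/6, 16 analytes with 5 out of
linear range, 2 batches, random batch offsets, one correlated block per
pathway, and a small outlier fraction).

# Pipeline and determinism

`runPipeline()` orchestrates the arc from a config list or YAML/JSON
file, writing every artifact (cleaned panel, cleaning report, model,
envelope, permutation, statistics table, networks, resolved config) plus
a manifest with the package version, master seed, config hash, and a
per-file content hash (32-bit FNV-1a; change detection, not
cryptography). A single master seed derives each stochastic stage's seed,
and no timestamps are written, so identical seeds yield byte-identical
manifests — the property the acceptance suite checks end-to-end.

# Validation summary

The test suite validates each stage against independent oracles and
known-truth simulations: the NIPALS LV1 weight against a direct SVD;
batch correction against `limma::removeBatchEffect`; Dunnett against
`mvtnorm`'s multivariate-t integration and its k = 2 t-test limit; Tukey
against `stats::TukeyHSD`; permutation p uniformity under the global
null (300 datasets × 200 shuffles); planted-signature and outlier
recovery rates; network FDR under null-plus-block simulations; and
byte-identical manifests across repeated seeded runs. Problem sizes in
the tests mirror the intended use: ~24–53 samples, 10–32 analytes.
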