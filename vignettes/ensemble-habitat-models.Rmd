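---
title: "Methods: ensemble habitat suitability models for burned forest"
author: "firehsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat suitability models for burned forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `firehsi`, the
assumptions behind it, the defaults and why they are set where they are,
and the numerical choices a user auditing results will want to know about.

## The modelling problem

A burned-forest nesting specialist uses 30-m pixels whose suitability is
believed to depend on burn severity (`dnbr`), slope orientation
(`cosasp`), and prefire canopy cover summarized at a nest-site scale
(`loccc`, 1-ha window) and a territory scale (`landcc`, 1-km-radius
window).  Nest observations exist only inside surveyed units at a handful
of calibration fires; predictions are wanted at many unsurveyed fires,
some of them environmentally unlike anything surveyed.  Rather than
betting on one model, an ensemble of eight structurally different models
is fitted, each pixel is classified suitable/unsuitable by every model,
and the count of "suitable" votes (0–8) is the prediction.  Two
diagnostics summarize whether the ensemble behaves the way a useful
predictor should:

1. within surveyed units, the proportion of pixels containing nests should
   rise with the ensemble count;
2. across locations, model agreement should *fall* with the location's
   median environmental distance from the surveyed environmental space,
   reflecting honest loss of confidence in no-analogue environments.

## Model families and their assumptions

**Weighted logistic regression (WLR).**  A resource selection model:
nest pixels versus available pixels, one model per calibration location.
The likelihood is the case-weighted binomial log-likelihood with used rows
at weight 1 and available rows at weight `n_used/n_available`, which gives
both classes equal total weight; with equal class sizes the fit reduces
exactly to ordinary logistic regression (this identity is a unit test).
The weighting removes the influence of the arbitrary available-sample
size; it assumes availability is sampled representatively from the survey
unit.  Fitting is by iteratively reweighted least squares
(`stats::glm.fit`); covariates are z-scored internally on the pooled
sample for conditioning, and coefficients are reported back on the
original scale.  Model selection fits all 16 covariate subsets (including
intercept-only) and ranks by AICc with effective n = the unweighted row
count, n_used + n_available.  Effective sample size under weighting is a
genuinely open question; the row count is the conservative, auditable
choice and is stored on every fit.  Separation is flagged (non-converged
IRLS or |standardized coefficient| > 15) and flagged subsets are excluded
from the ranking with a message rather than silently ranked on a
divergent likelihood.

**Partitioned Mahalanobis D².**  A distance model: suitability is
similarity to the multivariate mean of nest pixels, irrespective of
availability.  Nest covariates are standardized by the nest sample
mean/SD and the *correlation* matrix is eigendecomposed — correlation
rather than covariance because the covariates live on wildly different
scales (hundreds of dNBR units versus proportions).  Components are
ordered by **ascending** eigenvalue and partition *k* sums
(component score)²/eigenvalue over the *k* smallest-variance components:
minimum-variance components are the directions in which nest sites are
most alike, i.e. the most consistent habitat requirements.  At k = k_max
the statistic equals the classical Mahalanobis D² (tested against the
explicit inverse-covariance quadratic form to 1e-8).  D² is rescaled to
an HSI by the upper-tail χ²_k probability, which is 1 exactly at the nest
mean, strictly decreasing, and makes the k_max model the classical D²
p-value model.  The candidate set couples burn severity (always included)
with cosine aspect and the canopy-cover block (`loccc` + `landcc`
together), crossed with every feasible partition — ten candidates, the
count logged rather than hard-coded.  Production fits average 100
replicates, each fitted to an equal-representation subsample of 28 nests
per calibration location, so no location dominates the nest mean;
evaluation couples the same subsampling with five-fold cross-validation
(100 × 5 = 500 validation replicates) and records withheld-nest median
HSI and AUC against available pixels.  Candidate selection reports the
Pareto-nondominated set over (median nest HSI, AUC) so the final choice
among front members is transparent.

**Maximum entropy.**  A presence–background model.  Features (linear,
quadratic, pairwise products; threshold/hinge features are deliberately
out of scope) are min–max scaled to [0,1] on the background sample, and
the fit maximizes the concave penalized objective
`mean_pres(λ·f) − log mean_bg(e^{λ·f}) − Σ_j β_j|λ_j|`.  The default
regularization is the published schema re-expressed directly:
β_j = multiplier × s_class × sd_bg(f_j)/√n_presence with s = 1.0 for
linear/quadratic and 1.2 for product features (the original software's
sample-size interpolation tables are not reproduced).  At β = 0 the
fitted background expectation of each feature equals its presence mean (a
moment condition tested against a one-dimensional root-finding oracle);
at β > 0 the KKT box |E_q f − mean_pres f| ≤ β holds with equality on
active features.  The logistic output assumes a prevalence of 0.5:
HSI = q·e^H/(1 + q·e^H), so a model with no active feature scores 0.5
everywhere.  Variable contributions use permutation importance (mean drop
in training gain over 10 permutations, floored at zero, normalized to
100%) because the original software's path-dependent "training gain
contribution" is not reproducible without its exact optimizer path.
Backward exclusion removes the lowest-contribution covariate while the
mean five-fold validation AUC drops by at most 0.005.

## Thresholds, ensembles and novelty

Classification uses **HSI ≥ threshold → suitable**; the boundary
convention is fixed everywhere and pixels exactly at the threshold are
suitable.  The threshold maximizes predictive gain =
sensitivity − (1 − specificity) (identically the true skill statistic)
over all candidate thresholds — the distinct pooled scores plus one value
above the maximum — with nest and available scores **pooled** across
calibration locations before the scan; pooling is the most direct reading
of maximizing gain "across" locations (per-location averaging would be
the alternative).  Ties are broken toward the smallest threshold, i.e.
toward sensitivity, because the management cost of missing suitable
habitat exceeds that of over-predicting it.  The scan is verified against
an O(n²) brute-force oracle in the tests.

Ensemble counts are row sums of the 8-column binary classification
matrix.  Per-location summaries report the liberal (count ≥ 1) and
conservative (count = 8) suitable proportions and agreement
(count ∈ {0, 8}); at calibration locations these are compiled **outside**
survey-unit boundaries, matching the reporting convention for applied
predictions.  The nest-rate diagnostic is computed on surveyed pixels
only.  Environmental distance is
D = sqrt((x − μ)ᵀ Σ⁻¹ (x − μ)) with μ, Σ estimated from a survey-unit
reference sample balanced across calibration locations (default 5,000
pixels each); per-location distance samples are capped at 5,000 pixels.
All distance and HSI quantile summaries use the median-unbiased quantile
convention (type 8, α = β = 1/3); the convention is a deliberate choice —
none is implied by the definitions — and is centralized in one helper.

## The synthetic landscape generator

No field data are deposited, so the generator is a first-class module and
defines the study conditions everything else is tested under.

Per location it emulates: spatially autocorrelated covariate fields
(independent white-noise grids smoothed by a separable Gaussian kernel
whose SD is half the `smoothing_range_px`, default 4 px = 120 m); the
landscape-wide available-pixel moments (dNBR 327.8 ± 235.2, cosine aspect
0 ± 0.69, local canopy proportion 0.63 ± 0.42, landscape canopy
0.59 ± 0.19) with mild between-location variation; the strong
local/landscape canopy correlation (0.635) with all other
intercorrelations ≤ 0.3; one contiguous rectangular survey unit covering
35% of the grid; and nest pixels (28/44/36 at the three calibration
locations) sampled without replacement from survey-unit pixels with
probability proportional to a known truth.  The default truth is
linear-logistic in standardized covariates with per-SD coefficients
(cosasp 0.45, dnbr 0.85, loccc 0.50, landcc 0.35) chosen so that the
implied nest-vs-available mean shifts match the magnitudes a
burned-forest specialist exhibits (roughly +0.8 SD in burn severity,
+0.3–0.5 SD elsewhere); a unimodal-Gaussian truth is available for
optimum-seeking scenarios.  Application locations shift the dNBR mean
upward by 2–3.5 landscape SDs with slightly sparser canopy, emulating
fires that burned more severely than anything surveyed.

Three numerical choices matter:

* smoothed fields are *exactly* empirically standardized and
  orthogonalized (QR) before mixing through the Cholesky factor of the
  correlation matrix, so the pre-clip sample moments are exact and
  spatial autocorrelation cannot inflate the sampling error of the mean;
* bounded covariates are clipped to their ranges **after** generation,
  with the latent Gaussian moments solved numerically so the *clipped*
  variable matches the requested mean/SD, and the latent correlation
  inflated by the first-order Hermite attenuation factor so the
  *post-clip* correlation matches the request;
* per-location child seeds derive deterministically from the study seed
  and the location *name*, so adding a location never changes existing
  ones.

What the generator does **not** emulate: real fire-perimeter geometry,
salvage-logging mosaics, nest clustering beyond the suitability surface
(territoriality), temporal dynamics across postfire years, and
measurement error in the remote-sensing products.  Tests passing on these
landscapes therefore demonstrate the correctness and calibration of the
*machinery*, not the field accuracy of any particular fitted model.

## Numerical settings

| setting | default | notes |
|---|---|---|
| WLR IRLS | `glm.fit` defaults | separation flag at \|std coef\| > 15 |
| AICc effective n | rows, not summed weights | stored on the fit |
| Mahalanobis replicates | 100 (25 in quick runs) | equal-representation subsampling |
| zero-eigenvalue guard | 1e-10 | replicate rejected with diagnostic |
| Maxent convergence | objective Δ < 1e-9 **and** KKT violation < 1e-8 | max 5000 sweeps, step-halving on non-ascent |
| Maxent β multiplier | 1.0 | 0 disables regularization |
| threshold candidates | distinct scores + 1 above max | ties → smallest threshold |
| quantiles | type 8 | all median/interval summaries |
| distance reference | 5,000 px/location | covariance must be nonsingular (conditioning diagnostic) |

Degenerate inputs are handled explicitly: constant covariates are named
in errors (WLR) or dropped with a warning (Maxent features); all-identical
scores return zero gain with a warning; empty locations after survey-unit
exclusion are flagged `NA`; a singular distance covariance stops with the
condition number; locations with too few nests are named.

## Problem sizes

Default studies use three 120 × 120 calibration grids plus four 120 × 120
application grids (~101k pixels); repeated-seed checks (e.g. the sign of
the agreement–distance correlation over 20 seeds) use 60 × 60 grids with
25 Mahalanobis replicates.  Per-level nest proportions from a single
study rest on only 108 nest pixels, so the nest-rate correlation is
estimated from surveyed pixels pooled over three replicate studies.
These sizes are the package's chosen simulation scale: large enough for
the moment-fidelity and diagnostic properties to be sharp, small enough
to re-run casually.

## Known limitations

* The WLR weighting is the standard equal-class-total operationalization
  of use-availability weighting; alternative weightings (and whether
  available sites should be re-drawn per candidate subset) are plausible
  and would change AICc values slightly.
* The Maxent regularization constants approximate the published defaults
  schematically; exact coefficient-path parity with the original software
  is not a goal.
* Median nest HSI from the cross-validated Mahalanobis harness is biased
  slightly below 0.5 even for perfectly specified models, because D² at a
  withheld point with estimated mean/covariance follows a scaled-F rather
  than a χ² law at small training n; the bias vanishes as the subsample
  grows and the null-calibration test exercises exactly this.
* Ensemble counts weight all eight models equally; no stacking or
  accuracy weighting is attempted, by design — disagreement itself is the
  signal of interest.
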