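# firehsi

Ensemble habitat suitability modelling for a burned-forest nesting
specialist.

## The problem

Woodpeckers that specialize on recently burned conifer forest (the
archetype is the Black-backed Woodpecker, *Picoides arcticus*) nest almost
exclusively in post-wildfire snag stands, and the window for conserving
that habitat closes quickly once salvage logging begins.  Managers at a
fresh burn rarely have local nest data, so habitat must be predicted from
models calibrated at *other* fires — and no single model structure can be
trusted when extrapolating into environments the calibration data never
sampled ("no-analogue" conditions).  `firehsi` implements the ensemble
approach to this problem: fit several structurally different habitat
models, classify every 30-m pixel with each, and treat the *count of
models agreeing* as the prediction, with explicit diagnostics for where
and why the models diverge.

Every pixel carries four remotely sensed covariates:

| column   | meaning                                                        |
|----------|----------------------------------------------------------------|
| `cosasp` | cosine of slope aspect: +1 north-facing, −1 south-facing       |
| `dnbr`   | delta normalized burn ratio (burn severity index)              |
| `loccc`  | proportion of the 1-ha neighbourhood with >40% prefire canopy  |
| `landcc` | proportion of the 314-ha (1-km radius) neighbourhood with >40% prefire canopy |

## The models

All models score pixels on a common habitat suitability index (HSI) in
[0, 1]:

* **Weighted logistic regression** (`fit_wlr`): a resource selection model
  contrasting nest with available pixels.  Used rows get weight 1 and
  available rows weight `n_used/n_available`, so both classes carry equal
  total weight and the arbitrary available-sample size cannot tilt the
  coefficients.  All 2⁴ covariate subsets are fitted and ranked by
  AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) (`all_subsets_aicc`).
* **Partitioned Mahalanobis D²** (`fit_mahal`): a distance model.  Nest
  covariates are standardized, the nest correlation matrix is
  eigendecomposed, components are ordered by ascending eigenvalue, and
  partition *k* accumulates (score)²/eigenvalue over the *k* most
  "consistent" (smallest-variance) components; at k = k_max this is the
  classical D².  HSI = P(χ²_k > D²), so the nest multivariate mean scores
  exactly 1.  Fits average 100 replicates on equal-representation nest
  subsamples (28 per calibration location).
* **Maximum entropy** (`fit_maxent`): presence–background density
  estimation over linear, quadratic and product features scaled to [0,1],
  maximizing `mean_presence(λ·f) − log mean_background(e^{λ·f}) − Σβ_j|λ_j|`
  with the default regularization schema β_j ∝ sd_bg(f_j)/√n_presence.
  The logistic output at prevalence 0.5 is HSI = q·e^H/(1 + q·e^H), with q
  the background-normalized score and H the fitted background entropy.

Continuous scores become binary classifications at the threshold that
maximizes **predictive gain** = sensitivity − (1 − specificity) (the true
skill statistic), pooled across calibration locations
(`threshold_max_gain`).  The per-pixel **ensemble count** (0–8 under the
default roster of 3 WLR + 3 Mahalanobis + 2 Maxent models) is the headline
prediction; per-location summaries report the liberal (≥1 model) and
conservative (all models) suitable proportions and the agreement
proportion, and `environmental_distance` (a Mahalanobis distance from the
surveyed environmental space) quantifies novelty.

Because the original nest data are not deposited, the package ships a
synthetic-landscape generator (`simulate_study`) producing spatially
autocorrelated covariate fields with realistic means, SDs and
intercorrelations, survey units, and nests placed by a known suitability
truth — so the entire pipeline is testable end to end.

## Worked example

```r
library(firehsi)
st <- run_study(run_config(study = default_study(seed = 1)), verbose = FALSE)
print(st)
#> Ensemble habitat suitability study
#>    3 calibration + 4 application location(s), 100800 pixels
#>    8 models: wlr_calib_wa, wlr_calib_or, wlr_calib_id, mahal_2var_k2,
#>              mahal_3var_k3, mahal_4var_k4, maxent_3var, maxent_dnbr
#>   mean calibration AUC: 0.711
#>   nest rate vs ensemble level: Pearson r = 0.924
#>   agreement vs distance: Pearson r = -0.928
```

Reading the output: every model discriminates nests from available pixels
well above chance within the survey units (per-cell AUCs ~0.57–0.79, mean
0.711); the proportion of surveyed pixels containing nests rises almost
linearly with the number of models calling the pixel suitable (r = 0.92);
and location-level model agreement falls steeply as a location's median
environmental distance from the surveyed environments grows (r = −0.93) —
the severely burned "novel" locations are exactly where the resource
selection and distance models part company.

```r
head(st$location_summary[, c("location", "liberal", "conservative",
                             "agreement", "median_distance")])
#>   location liberal conservative agreement median_distance
#> 1 calib_wa   0.697        0.089     0.392            2.00
#> 2 calib_or   0.882        0.185     0.304            1.89
#> 3 calib_id   0.747        0.124     0.378            2.01
#> 4  novel_1   0.990        0.062     0.073            3.03
#> ...
plot(st, "agreement")   # agreement vs novelty
plot(st, "nest_rate")   # ensemble level vs nest occurrence
```

A thin command-line wrapper is included at `inst/cli/firehsi.R`
(`simulate`, `run-all`, `validate` subcommands).

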