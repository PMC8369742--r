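# gaprog

Box-Cox mixed-effects modelling of geographic-atrophy (GA) size
trajectories.

Geographic atrophy — the late atrophic stage of age-related macular
degeneration — is monitored through the lesion area (mm²) graded from
fundus autofluorescence images at irregular follow-up visits, often in both
eyes of a patient.  `gaprog` is for biostatisticians and ophthalmic
researchers who need to model such cohorts: it estimates how fast lesions
enlarge, which risk factors change the rate, when each eye's disease
started, and what size to expect at a future visit — all while respecting
the eye-within-patient correlation structure.

## The model

For eye *i* of patient *j* at follow-up time *t* (years), the
Box-Cox-transformed size `z = f_λ(y)` is assumed to grow linearly along a
clock that started at disease onset:

    z_ijt = (β + β_xᵀ x_i) · (Δ_i + t) + ε_ijt,
    Δ_i   = μ_Δ + γ_i + ζ_j,   γ_i ~ N(0, σ_Δ²),  ζ_j ~ N(0, σ_ζ²)

where `Δ_i` is the eye's (unobserved) disease age at study entry and `x_i`
holds time-constant risk-factor indicators.  The same `β, β_x` appear in
the fixed part, the time interactions and the random-effect loadings, so
the model is *not* an unrestricted mixed model; it is fitted by an
iterative working-covariable algorithm (`fit_with_covariables()`), with a
direct constrained-ML maximizer (`brute_force_ml()`) as a cross-check.  The
transformation parameter λ is chosen by grid search on Jacobian-corrected
AIC (`grid_search()`): λ = 1 is linear, 0.5 square-root (linear radius),
0 exponential growth.  Back-projection of fitted trajectories to a 0.05 mm²
threshold gives per-eye ages of onset (`estimate_onset()`); a smearing
estimator corrects the Jensen bias of back-transforming predictions to mm²
(`smearing_predict()`); and patient-cluster bootstrap percentile intervals
provide inference (`bootstrap_ci()`).  A synthetic-cohort generator
(`generate_cohort()`) simulates realistic bilateral cohorts from the
generative model so every method is testable without patient data.

## Worked example

```r
library(gaprog)

sim <- generate_cohort(synthetic_config(seed = 42))   # 101-patient cohort
sim$cohort
#> GA cohort: 101 patients, 156 eyes, 713 visits
#>   baseline size: mean 5.05 mm^2 (range 0.06 - 25.10)
#>   covariables: hyperchol_no, hypertension_no

gs <- grid_search(sim$cohort, grid = seq(0.25, 0.65, by = 0.05),
                  with_covariables = TRUE)
gs
#> Box-Cox grid search (with covariables), 9 lambda values
#>   lambda_opt = 0.45 (AIC = 2768.81 on the mm^2 scale)

fit <- gs$fits[[which(gs$table$lambda == gs$lambda_opt)]]
fit
#> GA trajectory model (with covariables, lambda = 0.45)
#> Fixed effects:
#>            intercept                 time    time:hyperchol_no
#>               0.4877               0.3919               0.1444
#> time:hypertension_no             mu_Delta
#>              -0.0988               3.3471
#> Random-effect SDs:
#>      eye  patient residual
#>   1.8068   3.7586   0.4252
#> logLik(z) = -713.046, logLik(y) = -1376.403, AIC(y) = 2768.81 [8 params]
#> iterations = 5, converged = TRUE
```

The cohort was simulated at λ = 0.45 with a baseline enlargement rate of
0.42 transformed units/year, +0.11 for eyes without hypercholesterolemia
and −0.09 for eyes without hypertension; the grid search recovers the
transformation and the fit recovers the rates (`mu_Delta`, the mean disease
age at entry in years, is weakly identified per cohort — see its bootstrap
interval below).

```r
summarize_onset(estimate_onset(fit, sim$cohort))
#>          statistic  value
#> 1   mean_onset_age  67.15
#> 2     sd_onset_age   7.93
#> 3 median_onset_age  67.01
#> 4   mean_entry_age  74.05
#> 5           n_eyes 156.00
#> 6      n_undefined   0.00
```

Eyes entered the study about 7 years after their estimated disease onset.

```r
rmsd_original_scale(fit, sim$cohort, seed = 1)   # smearing predictions, mm^2
#> [1] 1.25

bootstrap_ci(sim$cohort, gs$lambda_opt, B = 200, seed = 1)
#> Patient-cluster bootstrap (B = 200, 0 failed, 95% percentile CIs, lambda = 0.45)
#>           coefficient estimate ci_lower ci_upper
#>             intercept   0.4877  -2.4467   2.6395
#>                  time   0.3919   0.3517   0.4266
#>     time:hyperchol_no   0.1444   0.0983   0.1882
#>  time:hypertension_no  -0.0988  -0.1265  -0.0633
#>              mu_Delta   3.3471  -2.0634  10.1405
```

A command-line front end (`inst/cli/gaprog.R`) wraps the same workflow:

```sh
Rscript inst/cli/gaprog.R simulate --out-dir sim --seed 42
Rscript inst/cli/gaprog.R fit --input sim/cohort.csv --out-dir out --bootstrap 200
```

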