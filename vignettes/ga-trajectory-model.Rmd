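---
title: "Modelling geographic-atrophy size trajectories with gaprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographic-atrophy size trajectories with gaprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaprog)
```

## The scientific problem

Geographic atrophy (GA) is the late atrophic stage of age-related macular
degeneration.  Its clinical course is tracked by the lesion area (mm^2)
measured on fundus autofluorescence images at irregular follow-up visits.
Longitudinal GA studies have three awkward features that a trajectory model
must absorb at once:

* **Nonlinear growth.** Lesions do not enlarge linearly in mm^2; linear,
  square-root (linear radius) and exponential growth models have all been
  advocated.  Rather than committing to one, `gaprog` searches the Box-Cox
  family, which contains all three as special cases.
* **Unknown disease age.** Eyes enter a study at an unknown time after
  disease onset, so the baseline size mostly reflects how long the disease
  has been running, not how fast it runs.
* **Nested correlation.** Many patients contribute both eyes, each observed
  repeatedly, giving eye-within-patient clustering on top of repeated
  measures.

## The model

Let $y_{ijt} > 0$ be the lesion size of eye $i$ of patient $j$ at follow-up
time $t \ge 0$ (years since that eye's baseline visit), and let
$z_{ijt} = f_\lambda(y_{ijt})$ with the Box-Cox transform

$$ f_\lambda(y) = \begin{cases} (y^\lambda - 1)/\lambda & \lambda \neq 0 \\
\log y & \lambda = 0. \end{cases} $$

The core assumption is that, on the $\lambda$ scale, every eye grows along a
common linear clock that started at its (unobserved) disease onset: with
$\Delta_i$ the disease age of eye $i$ at study entry,

$$ z_{ijt} = (\beta + \beta_x^\top x_i)\,(\Delta_i + t) + \varepsilon_{ijt}, $$

where $x_i$ is a vector of time-constant, eye-level covariables (binary risk
factors coded so that 1 marks the *absence* of the factor) and
$\beta + \beta_x^\top x_i$ is the eye's total enlargement rate.  Writing
$\Delta_i = \mu_\Delta + \gamma_i + \zeta_j$ with independent Gaussian eye
and patient effects $\gamma_i \sim N(0, \sigma_\Delta^2)$,
$\zeta_j \sim N(0, \sigma_\zeta^2)$ yields a mixed-effects model — but not a
standard one: the same quantities $\beta, \beta_x$ appear multiplicatively
in the fixed part, the covariable interactions, and the loadings of both
random effects.

### Without covariables

Setting $\beta_x = 0$ and absorbing $\beta\Delta_i$ into
$\theta_i \sim N(\mu_\theta, \sigma_\theta^2)$ gives the unconstrained
nested random-intercept model

$$ z_{ijt} = \mu_\theta + \beta t + \zeta_j + \alpha_i + \varepsilon_{ijt}, $$

fitted directly by ML ([`fit_no_covariables()`]).  This is the model used in
the transformation grid search by default.

### With covariables: the working-covariable algorithm

The constrained model is fitted by iterating two steps
([`fit_with_covariables()`]):

1. compute the **working covariable**
   $\tilde{x}_i = \hat\beta + \hat\beta_x^\top x_i$ (initially
   $\tilde{x}_i = 1$);
2. fit, by exact ML, the linear mixed model
   $$ z_{ijt} = \beta_0 + \beta t + \beta_x^\top x_i t +
      \mu_\Delta \tilde{x}_i + \tilde{x}_i\gamma_i + \tilde{x}_i\zeta_j +
      \varepsilon_{ijt}, $$
   in which $\tilde{x}_i$ is a *known* per-eye loading, and read off new
   $(\hat\beta, \hat\beta_x, \hat\mu_\Delta)$.

Iteration stops when the maximum relative coefficient change falls below
`tol` (default `1e-6`, relative denominator $|\theta| + 10^{-8}$), with a cap
of 50 outer iterations; on the default synthetic cohorts convergence takes
well under 20.  A fixed *stability intercept* $\beta_0$ is included by
default; it decouples the fit from the constraint that estimated random
effects average to zero and is reported (it should be near 0).  A
`include_stability_intercept = FALSE` switch exists for strict-model
experiments; it is also what makes the zero-covariable nesting
($\mu_\theta = \beta\,\mu_\Delta$) exact, because with the intercept present
an all-constant $\tilde{x}_i$ would be collinear with it.

### How the inner fit is computed

Each inner fit maximizes the exact marginal Gaussian likelihood over
per-patient blocks.  For patient $j$ the covariance of the stacked responses
is
$\sigma_\varepsilon^2 I + \sigma_\zeta^2 w w^\top +
\sigma_\Delta^2\,\mathrm{blockdiag}_i(w_i w_i^\top)$
with $w$ the row vector of loadings.  The residual variance and all fixed
effects are profiled out in closed form (GLS), leaving a two-dimensional
search over the variance ratios
$\psi_\Delta = \sigma_\Delta^2/\sigma_\varepsilon^2$,
$\psi_\zeta = \sigma_\zeta^2/\sigma_\varepsilon^2$ on the log scale, handled
by a compiled Nelder-Mead.  A Woodbury/determinant-lemma factorization
reduces each likelihood evaluation to tiny $q \times q$ solves ($q = 1 +$
eyes of the patient), with all row-level sums precomputed once per design —
this is what makes $10^4$-fit bootstrap experiments routine.  Numerical
choices:

* variance ratios are clamped to $e^{\pm 30}$; a fitted SD below $10^{-6}$
  is reported as 0 with a boundary flag;
* rank-deficient fixed-effect designs (e.g. an all-zero covariable column)
  drop the aliased columns, report their coefficients as 0, and record them
  in `fit$aliased`;
* an exact-fit guard floors the profiled residual sum of squares, so
  noise-free data return $\hat\sigma_\varepsilon \approx 0$ rather than a
  degenerate likelihood;
* ML throughout, never REML: AIC comparisons across transformation
  parameters require it.

Random-effect point predictions are the conditional (posterior) modes given
the ML parameters, obtained from a closed-form GLS solve per patient block
(`conditional_modes()`); for the unconstrained model they coincide with
lme4's BLUPs, which the test suite uses as an independent oracle.

### The iterative fixed point is not the exact constrained MLE

`brute_force_ml()` maximizes the same likelihood with the constraint
$\tilde{x}_i = \beta + \beta_x^\top x_i$ imposed *inside* the objective.
The working-covariable fixed point satisfies the likelihood's stationarity
conditions only in the directions spanned by the inner design: the gradient
through $\tilde{x}_i$ — the $\mu_\Delta\tilde{x}_i$ mean term in the
per-covariable directions and the random-effect loadings — is not zero
there.  Empirically the two solutions agree closely at cohort sizes of ~100
patients and both recover the generative parameters without bias, but on
small cohorts (~20 eyes) log-likelihood differences of order 0.1–1 and
coefficient differences of several percent occur.  The iterative algorithm
is the package's primary fitter because it is fast, stable and matches
established practice; the brute-force oracle is kept for verification, and
this discrepancy should be kept in mind when the two are compared at tight
tolerances.

## Choosing the transformation

`grid_search()` fits the model at each $\lambda$ on a grid (default 0.05 to
1.50 in steps of 0.05, plus the log model $\lambda = 0$, spanning the three
literature growth models) and compares AIC **on the original scale**: by the
density transformation theorem

$$ \ell_y = \ell_z + (\lambda - 1)\sum \log y, $$

so $\mathrm{AIC}_y = -2\ell_y + 2\,n_\mathrm{params}$.  The parameter count
includes the estimated fixed effects, the two variance components and the
residual variance; $\lambda$ itself is fixed within each fit and not
counted (a constant offset cannot change the argmin).  Ties break toward
the smaller $\lambda$.  Failed fits at individual grid points are recorded
and skipped; only total failure is an error.

## Age-of-onset estimation

Clinical onset is defined as the lesion size `threshold_mm2` (default 0.05
mm^2, the area of the 250 µm minimum diameter used for diagnosis).  Solving
the fitted mean trajectory of each eye for the time at which it crosses the
transformed threshold gives, in the covariable model,

$$ \hat t_0 = \frac{f_\lambda(\text{thr})}{\tilde{x}_i} -
   (\hat\mu_\Delta + \hat\zeta_j + \hat\gamma_i), $$

and $(f_\lambda(\text{thr}) - (\hat\mu_\theta + \hat\zeta_j +
\hat\alpha_i))/\hat\beta$ without covariables.  $\hat t_0$ is negative for
onset before study entry, and the onset age is
`age_at_baseline + t0` — adding the *signed* $\hat t_0$, which is the only
convention under which estimated onset ages land below entry ages.  The
estimated disease age at entry is
$\hat\Delta_i = \hat\mu_\Delta + \hat\zeta_j + \hat\gamma_i$; a threshold
with $f_\lambda(\text{thr}) = 0$ (i.e. 1 mm^2) gives $\hat t_0 =
-\hat\Delta_i$ exactly.  `summarize_onset()` reports both mean and median
onset ages, since with skewed per-eye estimates the two can differ
noticeably.  Eyes with a vanishing enlargement rate have no defined onset
and are returned as `NA` with a reason, never dropped silently.

## Prediction on the mm^2 scale

The model is linear only on the transformed scale.  Because the inverse
transform is convex for $\lambda < 1$, the naive estimate
$f_\lambda^{-1}(\hat z)$ *under*-estimates the conditional mean size
(Jensen's inequality).  `smearing_predict()` corrects this with a smearing
estimator: draw $r$ residuals (default 10,000) with replacement from the
fitted model's empirical residual pool, add them to $\hat z$, back-transform
and average.  One shared draw set is used for all targets, so predictions at
different visits are perfectly comparable and the cost is one pool draw per
run.  Draws for which the inverse does not exist
($\lambda \hat z + \lambda\varepsilon + 1 \le 0$) are dropped and counted
(`n_dropped`; a warning fires when any target loses more than 1%), and a
target losing all draws is returned as `NA`.  `naive_backtransform()` is
kept deliberately so the Jensen gap can be quantified;
`rmsd_original_scale()` and `rmsd_lambda_sweep()` evaluate the fit on the
original scale, and `predict_next_observation()` runs the held-out
experiment: each eye with at least `min_visits` (default 4) visits has its
last visit removed, **one** shared training model is fitted to everything
that remains, and the held-out sizes are smearing-predicted with the
training fit's random-effect modes.  A single shared training fit (rather
than one refit per eye) is a deliberate choice for determinism and cost; it
is slightly conservative, because each eye's own held-out point was removed
from its random-effect estimate.

## Bootstrap inference

`bootstrap_ci()` resamples *patients* with replacement — the outermost
exchangeable unit — carrying each sampled patient's eyes and visits intact
and giving duplicates fresh identifiers, then refits at fixed $\lambda$
(re-selecting $\lambda$ per replicate would change the estimand) and forms
percentile intervals.  Replicate fits are warm-started from the full-data
fit; failures are counted and more than 10% of them abort the analysis.
Percentile intervals are the simplest defensible choice here; with the
heavy-tailed $\hat\mu_\Delta$ distribution (below) they can exclude the
point estimate, which is why that property is not asserted anywhere.

## The synthetic cohort generator

Because real GA cohorts are not redistributable, `generate_cohort()` draws
cohorts from the generative direction of the covariable model:
$z = \tilde{x}_i(\mu_\Delta + \gamma_i + \zeta_j + t) + \varepsilon$, then
$y = f_\lambda^{-1}(z)$.  The defaults describe a realistic modern GA
natural-history cohort: 101 patients, 48.5% bilateral; visit counts per eye
drawn from {2: 24.75%, 3: 22.78%, 4: 22.78%, 5–9: 5.94% each}; lognormal
visit spacing with median 0.9 years and `sdlog` 0.4 (a choice — per-visit
schedules are never published — placing mean follow-up near 3.4 years);
baseline age $N(75.61, 7^2)$ years (the SD is likewise a choice);
prevalences 0.71 / 0.44 for the absence of hypercholesterolemia /
hypertension; and generative parameters $\lambda = 0.45$, $\beta = 0.42$,
$\beta_x = (0.11, -0.09)$, $\mu_\Delta = 4.74$, $\sigma_\Delta = 1.83$,
$\sigma_\zeta = 4.03$, $\sigma_\varepsilon = 0.42$.

**Positivity and truncation.** For $\lambda > 0$ the transformed scale has a
hard support bound $z > -1/\lambda$, and measured lesions cannot fall below
a floor (`floor_mm2`, default 0.05 mm^2 — the clinical onset size; observed
cohorts likewise contain no smaller lesions).  Sub-floor rows are repaired
by redrawing the residual (up to 100 times); an unrepairable row triggers a
redraw of the eye (fresh $\gamma_i$), and an unrepairable eye a redraw of
the patient (fresh $\zeta_j$).  This mirrors the truncation that inclusion
criteria impose on real cohorts, and it has measurable consequences that
users of the generator should know:

* at the default parameters ~2–3% of eyes are affected (the counts are
  reported), and the AIC-selected $\hat\lambda$ acquires a *downward bias of
  about one 0.05 grid step*: over repeated default cohorts generated at
  $\lambda = 0.45$, the modal selection is 0.40.  Moving the generative mean
  far from the boundary removes the effect entirely, and the package's
  Jacobian-corrected likelihood matches lme4 point-by-point, so this is a
  property of truncated Box-Cox data, not of the implementation.  Any study
  whose smallest observed lesions sit near the detection limit should expect
  the same compression;
* $\hat\mu_\Delta$ is weakly identified when the stability intercept is
  estimated (the intercept and the $\tilde{x}_i$ regressor are nearly
  collinear when covariables induce only a few distinct $\tilde{x}$ values):
  its per-cohort sampling distribution at the default design has an SD of
  about 3 years and a mild upward bias (~0.25 years).  The identified
  combination $\beta_0 + \beta\mu_\Delta$ is estimated tightly;
* the patient-level SD is recovered with a slight downward shift (~3%),
  the usual ML small-sample behaviour plus truncation.

What the generator does **not** emulate: grading/measurement error distinct
from $\varepsilon$, informative dropout, floor-censored recording (values
are redrawn, not clamped), covariable dependence between the two risk
factors, or any image-level structure.  Passing tests on these cohorts
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions, not robustness to real-data artefacts.

## Problem sizes used in the tests and the acceptance script

The test suite runs recovery at 20 default cohorts (coefficient recovery
within 3 Monte-Carlo SEs), the transformation-recovery experiment at 10
cohorts, oracle comparisons on 10 cohorts of ~22 eyes, and bootstrap
coverage over 50 simulations at $B = 200$.  `scripts/acceptance.R` uses 10
cohorts for the transformation experiment and 1500 replicates for the
coefficient means; the larger count is purely to shrink the Monte-Carlo
error of the reported means (the $\hat\mu_\Delta$ replicate SD of ~3 years
makes small-replicate means noisy).  All sizes are package choices made for
statistical resolution.

## Known limitations

* Time-varying covariables are not supported; the working covariable would
  become visit-specific, which changes the algorithm.
* The iterative fixed point differs from the exact constrained MLE at small
  sample sizes (quantified above).
* No prediction intervals: smearing propagates residual noise only, not
  parameter uncertainty.
* Individual onset ages come without uncertainty intervals; only
  cohort-level summaries are reported.
* The bootstrap keeps $\lambda$ fixed, so transformation-selection
  uncertainty is not propagated.
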