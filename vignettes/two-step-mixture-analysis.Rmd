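---
title: "Two-step mixture analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mixture analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfalasso)
```

## The statistical problem

Chemical-mixture epidemiology routinely measures 10–50 correlated exposure
variables (often metals in blood, serum, and urine) on a few hundred
participants, with a continuous health outcome or biomarker. Analyses must
reduce dimension, accommodate intercorrelation, quantify effect sizes, and
— increasingly — detect pairwise interactions among exposures, for which
the candidate set grows quadratically. `rfalasso` implements a two-step
workflow for this setting and the comparators needed to judge it.

## The model and the two steps

The estimation target is linear in the (standardized) exposures and,
optionally, their pairwise products:

$$y_i = \beta_0 + \sum_j x_{ij}\beta_j + \sum_{a<b} x_{ia}x_{ib}\beta_{ab}
  + \varepsilon_i.$$

**Step 1 — screening.** A regression random forest is grown on the main
effects (bootstrap-sampled trees, random candidate subsets per split) and
each variable is scored by permutation importance: the mean increase in a
tree's out-of-bag mean squared error when that variable's values are
permuted. Variables scoring above zero — i.e., demonstrably better than
noise — are retained by default (`select_by_vimp(rule = "positive")`);
`top_k` and `frac_of_max` rules exist for sensitivity analysis, since no
single cutoff is canonical. Because the forest splits on any marginal or
interaction-borne association, the screen retains variables whose effect on
the outcome is nonlinear or interactive, not only linear. The comparator
screen is a single regression tree pruned by cost-complexity with the
penalty chosen by 10-fold cross-validation under the one-standard-error
rule; the variables appearing in any split of the pruned tree are kept. A
root-only pruned tree (the typical null-data outcome) yields an empty
screen, which falls back — loudly — to the unscreened single-step analysis
rather than failing.

Confounders never enter the screen: they are forced into every stage-two
model with penalty weight zero, and they are never crossed into product
terms.

**Step 2 — adaptive lasso.** On the retained design the package minimizes

$$\lVert y - \textstyle\sum_j x_j\beta_j\rVert^2
  + \lambda \sum_j w_j\lvert\beta_j\rvert,
  \qquad w_j = \lvert\hat\beta_j^{\mathrm{initial}}\rvert^{-\gamma},$$

a weighted-L1 criterion whose per-coefficient weights shrink strong
initial signals less and weak ones more, restoring selection consistency
that the plain lasso lacks under correlation. Initial estimates are OLS
when the design is well-conditioned and ridge (penalty chosen by an
internal 5-fold cross-validation) whenever interaction columns are present
or the condition number exceeds 10³, since products of correlated columns
are themselves strongly collinear.

Interactions are expanded *after* screening for the two-step methods (only
products among retained variables are candidates) and over all candidates
for the single-step comparator; `interaction_scope = "all"` overrides this
for sensitivity analysis. Product columns are computed from standardized
main effects and re-standardized, so every penalized column enters on a
common scale; whether to re-standardize products is a genuine choice, and
the package does (an assumption, recorded here).

## Tuning parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n_trees` | 1000 | forest size; importance SDs shrink with more trees |
| `mtry` | max(⌊m/3⌋, 1) | regression-forest convention |
| `min_node` | 5 | regression default |
| `gamma_grid` | 0.5, 1, 2 | standard candidate exponents for the adaptive weights |
| λ path | 100 points, λ_max → 10⁻⁴λ_max, log-spaced | λ_max = maxⱼ 2\|xⱼᵀy\|/wⱼ zeroes every penalized coefficient |
| `K` (tuning and performance CV) | 10 | equal-size random folds |
| `weight_cap` | 10⁶ | keeps wⱼ finite when an initial estimate is exactly 0; capped variables are effectively unselectable |
| `max_missing_frac` | 0.40 | columns with *more than* 40% missing + censored cells are dropped (strict inequality) |

The pair (γ, λ) is tuned jointly: for each γ, the weights define a λ path,
and one shared fold assignment scores the whole (γ, λ) surface so its
values are comparable. The fit at the CV-minimizing pair is refit on all
data; exact ties break toward the larger λ, then the smaller γ, favoring
sparsity deterministically.

## Cross-validation bookkeeping

Three numerically consequential choices:

* **Fold-internal standardization.** Column means/SDs are estimated on
  each training fold and applied to its held-out fold; nothing held out
  leaks into the fit. The final refit standardizes on all data.
* **Weight provenance.** The adaptive weights are built once from
  full-data initial estimates and shared across the tuning folds
  (`cv_weights = "full"`, the default) — the fixed-penalty-factor
  convention of cross-validated penalized regression, in which the weights
  are part of the estimator definition and only (γ, λ) are tuned.
  `cv_weights = "per_fold"` recomputes initial estimates and weights
  inside each training fold and evaluates each fold at the same *relative*
  depths of its own λ_max (fold weights carry their own scale, so absolute
  grids would not correspond). The trade-off is real: full-data weights
  let a little of the held-out information into the tuning surface, which
  loosens selection on null data, while per-fold weights are fully nested
  but noisier and, in the package's replicate studies, inflate the
  two-step workflow's selected support. The default follows the
  weights-once convention; the acceptance suite records the consequences
  of that choice rather than hiding them. The outer *performance*
  cross-validation re-runs everything, weights included, inside each
  training fold regardless.
* **λ rescaling across sample sizes.** The objective carries no 1/n
  factor, so a given λ is relatively stronger on a 90%-sized training fold
  than on the full data. Fold-level solves therefore scale λ by
  n_train/n, keeping the penalty-to-RSS ratio consistent between the CV
  surface and the final refit. For the same reason λ values here are 2n
  times those of software that minimizes (1/2n)RSS + λ‖β‖₁;
  `lambda_to_glmnet()` converts.

Performance metrics (R², adjusted R² with p = number of nonzero estimated
coefficients excluding the intercept, MSE with divisor n, and the
fold-size-weighted cross-validated errors) are computed under a CV plan
shared across all compared methods. By default the *entire* procedure —
screening, expansion, weight construction, (γ, λ) tuning — is re-executed
inside each training fold (`cv_mode = "nested"`), so the reported MSPE is
free of selection leakage; `"fixed-screen"` screens once on all data and
only re-tunes per fold. The cross-validated training error `mse_cv` is
defined as the fold-size-weighted mean of the per-fold training MSEs — one
reasonable reading of a quantity whose construction is often left
unstated; the interpretation is recorded in the output metadata.

## The solver

The weighted-L1 objective is minimized by cyclic coordinate descent
(`src/cd_solver.cpp`): exact soft-threshold updates
βⱼ ← S(xⱼᵀr₋ⱼ, λwⱼ/2)/xⱼᵀxⱼ, a maintained residual vector, warm starts
down the λ path, and active-set iteration between full sweeps. Columns
with wⱼ = 0 receive plain least-squares updates, so confounders are
handled by the same code path. Convergence is declared on the gradient
scale: iteration stops only when the maximum violation of the
Karush-Kuhn-Tucker stationarity conditions falls below `tol` (10⁻⁹ for
final fits, 10⁻³ for path solves inside CV, where only the shape of the
CV curve matters). Every returned fit is therefore its own optimality
certificate, and the test suite checks the certificate explicitly, along
with agreement against an independent brute-force grid minimizer on small
problems, the OLS limit at λ = 0, and the orthonormal closed form.
λ_max carries a one-part-in-10¹⁰ upward rounding so that the all-zero
property at λ = λ_max holds exactly in floating point. Degenerate inputs
are contracts, not crashes: constant outcomes, zero-variance columns,
empty screens, and empty selected supports each have a defined behavior.

## Simulated designs and what they (do not) show

`dataset2_default()` is the package's reference design: n = 500, twenty
predictors in two independent equicorrelated blocks (ρ = 0.1 for
X1..X15, ρ = 0.05 for X16..X20), positive main effects on X1, X2, X12,
X15, negative on X9 and X16, one synergistic X1:X12 interaction, and unit
Gaussian noise. The six main-effect magnitudes and the interaction
coefficient are set equal and calibrated analytically so the true model's
population R² is 0.30: the closed-form signal variance under the
equicorrelated normal is β'Rβ for the linear part plus Isserlis-theorem
terms (Var(XₐX_b) = 1 + ρ²) for products — `signal_variance()` implements
it, and the test suite validates it against large-sample Monte-Carlo.
`correlation_sweep_config(rho)` replaces both block correlations for
studying behavior as collinearity grows; above ρ = 0.8 it warns, since no
selection method studied here remains reliable there.

`niehs_like()` emulates a prospective-cohort structure — seven correlated
exposures plus a confounder, with fixed potency ratios (β₁ = 2β₂ > 0,
β₅ = 4.5β₄ with both negative, β₇ > 0, β₃ = β₆ = 0) — as a *linear
surrogate*: the real dose-response surface such workshop datasets use is
not public, so this design demonstrates identifiability (on noiseless
draws the fitted ratios are exact to 10⁻⁶), not reproduction of any
external benchmark. More generally the generators draw from a Gaussian
copula with homoscedastic noise; real biomonitoring data are skewed,
left-censored, heteroscedastic, and missing not at random, so passing
tests here demonstrate correctness of the machinery, not robustness to
those features (the preprocessing module addresses them before modeling).

## Known limitations

* The confidence intervals from `refit_ols_ci()` are naive post-selection
  intervals: OLS on the selected columns, ignoring that the data chose
  them. Nominal coverage is verified by simulation only for supports fixed
  a priori; selective inference is out of scope and the documentation
  labels the intervals accordingly.
* CV-minimum tuning keeps prediction-optimal rather than
  selection-optimal penalties: on the reference design the two-step
  workflow typically carries one or two spurious variables alongside the
  true effects, so exact support recovery in a majority of replicates is
  not achieved — the strictest bar the acceptance suite asserts, and the
  one it documents as failing — while interaction detection and two-step
  parsimony hold. Users wanting harder sparsity can pass a stricter
  screening rule or examine the CV surface directly.
* The second stage is linear: a nonlinear exposure-response found by the
  forest will be kept by the screen but approximated linearly in the fit.
* Only pairwise products are considered; no grouped or hierarchical
  penalties (an optional strong-hierarchy filter exists, default off,
  since interaction-only detections are legitimate in this field).

## Problem sizes in the test suite

The suite exercises the claims at sizes a laptop handles in minutes, a
deliberate choice: 50 replicates for null-behavior and support-recovery
studies (n = 500, m = 20), 100 seeds for the correlation-range
distributional check, 400 replicates for interval coverage, and
n = 10⁵ draws for Monte-Carlo validation of the analytic variance
formulas. Each such size is stated in the corresponding test.
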