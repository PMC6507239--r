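# rfalasso

Two-step statistical analysis of chemical-mixture exposures: random-forest
variable screening followed by an adaptive lasso with two-dimensional
cross-validation.

## The problem

Biomonitoring studies measure dozens of correlated chemical exposures
(metals in blood, serum, and urine) on modest numbers of participants and
ask which exposures — and which pairwise interactions between them — drive a
continuous health outcome. Single-step penalized regressions tend to keep
too many variables and become unstable once all pairwise products enter the
design; single regression trees screen aggressively but unstably. This
package implements a two-step workflow for that setting, together with the
comparators needed to benchmark it:

1. **Screening.** A regression random forest ranks candidate exposures by
   permutation variable importance (VIMP): the increase in out-of-bag mean
   squared error when a variable's values are permuted. Variables with
   VIMP > 0 (or a top-*k* / fraction-of-maximum rule) pass to stage two;
   confounders bypass screening entirely. A CART screen (cost-complexity
   pruning, 1-SE rule) is provided as the comparator.
2. **Estimation.** The retained variables — optionally expanded with all
   pairwise products among them — enter an adaptive lasso:

   β̂ = argmin_β ‖y − Σⱼ xⱼβⱼ‖² + λ Σⱼ wⱼ|βⱼ|,   wⱼ = |β̂ⱼ^initial|^(−γ)

   with initial estimates from OLS (or ridge under multicollinearity) and
   the pair (γ, λ) tuned jointly by K-fold cross-validation over
   γ ∈ {0.5, 1, 2} and a 100-point log-spaced λ path. Confounders carry
   weight 0 and are never penalized. The solver is a coordinate-descent
   routine written for exactly this objective (note: no 1/2n factor, so λ
   is not numerically comparable to conventions that divide by 2n — see
   `lambda_to_glmnet()`).

Performance is reported as R², adjusted R², MSE, and fold-weighted
cross-validated errors, with the complete procedure (screening included)
re-run inside every training fold by default:

MSPE = Σₖ (nₖ/n) · Σ_{i∈Cₖ} (yᵢ − ŷᵢ)²/nₖ

Preprocessing utilities cover the standard exposure-table quality-control
chain: below-LOD imputation by LOD/√2, exclusion of variables with more
than 40% combined missing/censored cells, complete-case handling, and
log + z-score standardization.

## Worked example

Simulate the package's reference design — 500 samples, 20 predictors in two
equicorrelated blocks (ρ = 0.1 within X1..X15, ρ = 0.05 within X16..X20),
six true main effects (X1, X2, X12, X15 positive; X9, X16 negative) plus a
synergistic X1:X12 interaction, calibrated so the true model explains 30%
of outcome variance — then run the two-step workflow:

```r
library(rfalasso)

d   <- simulate_dataset(dataset2_default(), seed = 42)
res <- run_analysis(d$X, d$y, method = "rf_alasso", seed = 1)
res
#> Workflow: rf_alasso
#> Screen (rf): 14 variable(s) kept
#>   X12, X15, X16, X1, X2, X9, X19, X11, X6, X18, X7, X13, X5, X3
#> Adaptive lasso fit (two-dimensional CV)
#>   n = 500, p = 14; chosen gamma = 2, lambda = 0.2624
#>   support (8): X1, X2, X6, X9, X12, X15, X16, X19
#>   R2 = 0.296, adj R2 = 0.284, MSE = 1.007, MSE.CV = 1.004, MSPE.CV = 1.053 (K = 10, nested)
```

The screen discards a quarter of the candidates; the adaptive lasso then
recovers all six true effects (signs and magnitudes ≈ ±0.24 each) alongside
two small false positives — the fitted R² matches the design's 30% signal
share, and the cross-validated MSPE sits just above the noise variance of
1, as it should. `res$ci_table` holds the OLS-refit coefficients and naive
95% confidence intervals used for forest-plot-style reporting:

```r
subset(res$ci_table, term != "(Intercept)")
#>   term estimate     se ci_low ci_high
#> 2   X1    0.272 0.0473  0.179  0.3646
#> 3   X2    0.245 0.0453  0.156  0.3336
#> 4   X6   -0.114 0.0432 -0.199 -0.0295
#> 5   X9   -0.259 0.0445 -0.347 -0.1719
#> 6  X12    0.221 0.0448  0.133  0.3086
#> 7  X15    0.283 0.0477  0.189  0.3765
#> 8  X16   -0.215 0.0441 -0.302 -0.1288
#> 9  X19   -0.122 0.0458 -0.212 -0.0315
```

`compare_methods()` runs the full 3 × 2 grid (single-step adaptive lasso,
CART + adaptive lasso, RF + adaptive lasso; with and without pairwise
interactions) under one shared cross-validation plan. A thin command-line
wrapper with `simulate`, `analyze`, `compare`, and `preprocess` subcommands
is installed at `inst/cli/rfalasso-cli.R`.

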