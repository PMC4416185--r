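# matchedlasso

Sparse (Lasso) conditional logistic regression for individually matched
case-control and case-crossover data, built for registry-scale studies:
many strata, many binary exposures, few true effects.

## The problem

Matched designs pair each case with M controls that share matching factors
(or, in case-crossover studies, with the subject's own earlier control
periods). The standard analysis is conditional logistic regression: with
stratum-specific baseline odds `logit(pi_in) = alpha_n + u_in beta`,
conditioning on "exactly one case per stratum" eliminates every `alpha_n`
and leaves the conditional likelihood

```
L(beta) = prod_n 1 / (1 + sum_l exp(-x_ln beta)),    x_ln = u_case - u_control_l
```

a function of within-stratum covariate differences only. With hundreds of
candidate exposures, an L1 penalty `lambda * ||beta||_1` performs estimation
and variable selection at once:

```
beta_hat(lambda) = argmin  sum_n log(1 + sum_l exp(-x_ln beta)) + lambda ||beta||_1
```

The difference form makes the IRLS weight matrix diagonal, so each penalized
reweighted least squares step can be solved by cyclic coordinate descent on
the p x p Gram system `(X'WX, X'Wz)` — solver memory grows with the number
of predictors, not the number of person-periods, and the difference matrix
can be held sparse. Confounders (age, sex, chronic disease, ...) can be
declared unpenalized and are then always kept in the model. The penalty is
chosen on a decreasing lambda grid by stratum-wise 10-fold likelihood-based
cross-validation or BIC.

## A worked example

```r
library(matchedlasso)

# 400 matched pairs, six binary exposures (prevalence 25%), two true effects
d <- simulate_matched(n_strata = 400, n_controls = 1,
                      beta = c(0.9, -0.9, 0, 0, 0, 0),
                      prevalence = 0.25, seed = 42)

cv <- cv_clogit_lasso(d, n_lambda = 30, nfolds = 5, seed = 1)
glance(cv)
#> # A tibble: 1 × 5
#>   nfolds  seed lambda_selected df_selected cv_max
#>    <int> <dbl>           <dbl>       <int>  <dbl>
#> 1      5     1            3.51           3  -46.2

tidy(cv$selection)
#> # A tibble: 3 × 4
#>   term  estimate odds_ratio penalized
#>   <chr>    <dbl>      <dbl> <lgl>
#> 1 x1      1.39        4.01  TRUE
#> 2 x2     -1.04        0.352 TRUE
#> 3 x4     -0.0256      0.975 TRUE
```

Cross-validation keeps both true effects (plus one near-zero noise term, as
prediction-optimal Lasso selection tends to). The odds ratios (4.01, 0.35)
are the within-stratum multiplicative effects of each exposure on the odds
of being the case. `autoplot(cv)` draws the CV curve and `autoplot(cv$path)`
the coefficient trace along the penalty path.

Real data come in long format, one row per subject-in-stratum:

```r
md   <- read_matched("pairs.csv", stratum = "pair_id", case = "responsible",
                     unpenalized = c("age_65_70", "chronic"))
md   <- drop_rare_predictors(md, min_subjects = 10)
path <- clogit_lasso(md, n_lambda = 100)
sel  <- bic_select(path)
odds_ratios(sel)
```

A command-line interface covering the same pipeline is installed as
`exec/matchedlasso` (subcommands `fit` and `simulate`; see `--help`).

## Package layout

- `R/matched-data.R` — long-format ingestion and validation, rare-exposure
  filtering
- `R/differences.R` — the within-stratum difference matrix, concordant-set
  handling
- `R/likelihood.R` — conditional log-likelihood, gradient, IRLS weights
- `R/solver.R` — IRLS + cyclic coordinate descent + line search at fixed
  lambda
- `R/path.R` — lambda_max, grids, warm-started paths
- `R/selection.R` — cross-validation, BIC, odds-ratio tables
- `R/simulate.R` — matched and case-crossover generators with known truth
- `vignettes/matchedlasso-methods.Rmd` — model, algorithm and design notes
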