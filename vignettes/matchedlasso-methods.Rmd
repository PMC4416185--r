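---
title: "Sparse conditional logistic regression for matched data: model and algorithm"
author: "matchedlasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse conditional logistic regression for matched data: model and algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchedlasso)
```

## The model

Individually matched case-control and case-crossover studies group subjects
into $N$ strata (matched sets), each with one case and $M_n \ge 1$ controls.
Within stratum $n$, subject $i$ has covariates $u_{in}$ and the stratified
logistic model

$$\operatorname{logit}(\pi_{in}) = \alpha_n + u_{in}\beta,$$

where $\alpha_n$ is a stratum-specific baseline odds (the joint effect of
whatever the sets were matched on) and $\beta$ the log odds ratios of
interest. Conditioning on the fact that exactly one member of each stratum is
the case eliminates every $\alpha_n$: the probability that the observed case
is the case, given its stratum, is

$$\frac{e^{u_{0n}\beta}}{\sum_{l=0}^{M_n} e^{u_{ln}\beta}},$$

indexing the case as subject $0$. Writing $x_{in} = u_{0n} - u_{in}$ for each
control $i$ turns the conditional likelihood into

$$L(\beta) = \prod_{n=1}^{N} \frac{1}{1 + \sum_{l=1}^{M_n} e^{-x_{ln}\beta}},$$

a function of within-stratum *differences* only. For 1:1 matching this is
exactly a no-intercept binary logistic likelihood on the difference rows with
constant response 1. The package estimates $\beta$ by minimizing the L1
(Lasso) penalized negative log conditional likelihood

$$f(\beta) = \sum_n \log\Big(1 + \sum_{l} e^{-x_{ln}\beta}\Big) + \lambda \|\beta_{\mathcal P}\|_1,$$

where $\mathcal P$ is the set of penalized coefficients; forced confounders
(age, sex, chronic disease and the like) can be excluded from the penalty and
are then always retained.

## Why the difference form matters

The iteratively reweighted least squares (IRLS) approximation of the loss at
the current $\beta$ needs a weight matrix. On the difference scale that
matrix is *diagonal*, with entries

$$W_{in} = \frac{e^{-x_{in}\beta}}{d_n^2}, \qquad
z_{in} = x_{in}\beta + d_n, \qquad
d_n = 1 + \sum_l e^{-x_{ln}\beta},$$

and the identity $-X^tW(z - X\beta) = \nabla f_0(\beta)$ holds exactly
($f_0$ the unpenalized loss). On the undifferenced scale the weight matrix
has within-stratum off-diagonal blocks and every IRLS step would require a
block factorization. The diagonal form lets each reweighted Lasso subproblem
be posed purely through the Gram quantities $A = X^tWX$ ($p \times p$) and
$b = X^tWz$ ($p$-vector), so solver memory is $O(p^2)$ however many
person-periods the registry contributes, and $X$ can be held sparse when
exposures are rare.

For $M_n > 1$ this diagonal $A$ is *not* the exact Hessian of the loss (the
within-stratum cross-terms $-(\sum_l r_l x_l)(\sum_l r_l x_l)^t$ are
omitted; with $r_{in} = e^{-x_{in}\beta}/d_n$ the true Hessian is
$\sum_l r_l x_l x_l^t$ minus that outer product). We keep the diagonal form
deliberately: it is what makes the large-$N$ formulation cheap, and descent
is enforced by a line search rather than by curvature fidelity. The
consequences for convergence behavior are discussed below.

## The solver

At a fixed $\lambda$ the fit iterates:

1. compute $W$, $z$ and the Gram system $A$, $b$ at the current $\beta$;
2. solve the penalized weighted least squares problem
   $\min_\gamma \tfrac12\|W^{1/2}(z - X\gamma)\|^2 + \sum_j \lambda_j|\gamma_j|$
   by cyclic coordinate descent on $(A, b)$, with per-coordinate penalties
   $\lambda_j \in \{0, \lambda\}$ implementing forced covariates, warm-started
   at $\beta$; coordinates are swept in fixed column order (no randomization,
   for bit-reproducibility);
3. backtracking line search along $\Delta = \gamma - \beta$;
4. stop when the relative objective change falls below $\tau$ *and* the
   subgradient (KKT) residual falls below `kkt_tol`.

Numerical choices, with defaults and reasons:

* **Armijo slope.** The acceptance test is
  $f(\beta + t\Delta) \le f(\beta) + \alpha_1 t D$ with
  $D = g^t\Delta + \lambda(\|\beta + \Delta\|_1 - \|\beta\|_1)$, the descent
  measure of the composite (proximal-Newton) step. Using the bare $g^t\Delta$
  instead is tempting but wrong for a penalized objective: near the optimum
  the penalty's directional derivative cancels most of $g^t\Delta$, the bare
  slope overstates the attainable descent by orders of magnitude, and the
  search then rejects every step — we observed stalls at subgradient
  residuals around $10^{-2}$ on 1:2 data before adopting the composite form.
* **KKT stop** (`kkt_tol = 1e-4`). For 1:1 strata the diagonal weights are
  the exact Hessian, convergence is quadratic, and the relative-objective
  criterion $\tau = 10^{-8}$ alone lands on the optimum. For $M > 1$ the
  understated curvature makes the outer loop linearly convergent and the
  objective flattens out one to two orders of magnitude before the
  subgradient conditions hold, so convergence additionally requires the KKT
  residual — the maximal violation of
  $|g_j| \le \lambda$ (zero coefficients), $g_j = -\lambda\,\mathrm{sign}(\beta_j)$
  (active ones), $g_j = 0$ (forced ones) — to drop below `kkt_tol`. This
  roughly doubles the outer iteration count on 1:4 paths and is the price of
  returning certified optima with the printed diagonal weights.
* **Overflow safety.** Each stratum term is evaluated as
  $\log1p(\sum e^{-x\beta})$ with the per-stratum maximum exponent factored
  out once any exponent exceeds 30; weights are clamped below at
  $10^{-10}$ (`weight_floor`) and clamp events are counted in the fit
  diagnostics; $d_n$ is capped at $e^{700}$ so working responses stay finite
  near separation.
* **Degenerate coordinates.** A column with zero curvature ($A_{jj} = 0$,
  e.g. a predictor concordant in every stratum) is frozen at zero when
  penalized; for a forced covariate it is an error, since a collinear forced
  term has no unique estimate.
* **Other defaults.** $\alpha_1 = 0.01$, $\alpha_2 = 0.5$,
  `max_outer = 100`, `inner_tol = 1e-9` (largest coordinate change per
  sweep), `max_inner_sweeps = 10p + 100`, line-search floor
  $t_{\min} = 10^{-12}$ (below it the fit is flagged `converged = FALSE`).
  These are conventional values inside the admissible ranges
  $0 \le \alpha_1 \le 0.5$, $0 < \alpha_2 < 1$, $\tau > 0$.

## The regularization path

$\lambda_{\max}$ — the smallest penalty at which every penalized coefficient
is zero — equals the largest absolute penalized gradient coordinate at the
null model, $\max_j |\sum_n \sum_l x_{lnj}/(M_n + 1)|$ (the per-stratum
generalization of the fixed-$M$ formula, so variable stratum sizes are
handled). With forced covariates the reference point is instead the
forced-only maximum conditional likelihood fit, which guarantees the first
path point has empty penalized support — the $\beta = 0$ formula does not
once forced terms are present. The grid runs from $\lambda_{\max}$ down to
$\varepsilon\,\lambda_{\max}$ in `n_lambda` steps, log-spaced by default
($\varepsilon = 0.01$, `n_lambda = 100`): log spacing concentrates
resolution where the support changes. Each fit is warm-started at the
previous solution; the first starts from zero. A fit that fails at some
$\lambda$ (typically near-separation at tiny penalties — the operational
meaning of $\lambda_{\min}$) is flagged and excluded from model selection
rather than aborting the path. Grid endpoints are set exactly:
`exp(log(x))` rounding one ulp below $\lambda_{\max}$ is enough to activate
a spurious microscopic coefficient at the first path point.

## Model selection

*Cross-validation* shuffles **strata** (never rows — a matched set is one
observation of the conditional likelihood) into K near-equal folds by a
recorded seed, refits the path on each training set, and records the
held-out conditional log-likelihood
$-\sum_{n \in \text{fold}} \log(1 + \sum_l e^{-x_{ln}\hat\beta})$ per
$\lambda$. The selected $\lambda$ maximizes the fold mean; ties break toward
the larger, sparser penalty; $\lambda$ values that fail to converge in any
fold are excluded. "Likelihood-based" here means exactly the conditional
likelihood: it is the only likelihood a matched design makes available, and
held-out deviance would order the grid identically. An optional
one-standard-error rule is off by default.

*BIC* is $2 \cdot \text{nll} + \text{df}\,\log N$ with $N$ the number of
strata and df the count of nonzero penalized coefficients plus forced
covariates. $N$ (not the row count $NM$) is the right sample size because
each stratum contributes a single multinomial observation.

Odds ratios are reported as $e^{\hat\beta_j}$ for every retained
coefficient; penalized coefficients shrunk exactly to zero are omitted from
the table, forced covariates are always shown.

## The simulator

`simulate_matched()` draws, per stratum, $M+1$ covariate vectors — binary
exposures with a given prevalence (optionally with within-stratum
exchangeable correlation $\rho$, implemented by letting each subject copy a
shared stratum-level draw with probability $\sqrt\rho$, which gives pairwise
correlation exactly $\rho$ at unchanged prevalence), or standard gaussians —
and then selects the case with probability
$e^{u_{in}\beta}/\sum_l e^{u_{ln}\beta}$ (a Gumbel-max draw, which is an
exact softmax sample). That is precisely the conditional probability the
estimator models, so the stratum intercepts $\alpha_n$ cancel by
construction: the package draws them anyway (after all data-determining
draws, so they cannot perturb the stream) and attaches them as an attribute,
making "the estimates do not depend on $\alpha_n$" a testable structural
fact rather than an approximation. Parameter-recovery experiments on this
generator therefore test the solver, not a rejection-sampling scheme.

`simulate_case_crossover()` makes each subject a stratum of `n_periods`
person-periods whose exposures follow a stationary first-order binary chain
with marginal prevalence $\pi$ and lag-one correlation $\phi$
($P(1\mid 1) = \pi + \phi(1-\pi)$, $P(1\mid 0) = \pi(1-\phi)$); the case
period is again a softmax draw. $\phi = 0$ reduces to independent draws;
$\phi = 1$ makes every stratum concordant and is the degenerate edge the
concordance filter is tested against.

What the generator does *not* emulate: drug-class structure and realistic
co-prescription correlation networks, exposure measurement error, loss of
controls correlated with exposure, or matching on unobserved factors.
Passing recovery tests on this generator shows the estimator solves the
conditional model it targets; it does not validate the conditional model
against real registry complications.

## Data handling choices

* Covariates are **not standardized by default**: the intended predictors
  are binary exposures on a common scale, where shrinking by empirical
  standard deviations would silently upweight rare exposures. An opt-in
  `standardize = TRUE` scales penalized columns to unit variance on the
  difference scale and back-transforms the coefficients.
* Concordant strata (case and controls identical on every covariate)
  contribute a constant $\log(M_n+1)$ to the loss and nothing to the
  gradient; dropping them (`drop_concordant = TRUE`, off by default) changes
  reported likelihood values but provably never the estimates, and the test
  suite asserts both facts.
* Rarely observed exposures can be removed up front
  (`drop_rare_predictors()`, threshold in subjects); forced covariates are
  never removed.
* The case is identified by the indicator column, never by row position;
  within-stratum control order is preserved from the input; strata are
  ordered by first appearance. Variable stratum sizes (lost controls) are
  supported throughout, with every $M$-dependent formula applied per
  stratum.
* Case-crossover data reuse a subject across periods; rows are treated as
  independent given the stratum, exactly as the conditional likelihood does.

## Problem sizes used in the shipped experiments

The experiment scripts and acceptance checks in this package use: solver
cross-checks against an independent proximal-gradient optimizer on 200
random designs with $N \le 30$, $M \in \{1,\dots,4\}$, $p \le 5$ across
penalty levels $\{0, 0.1, 0.5, 1\}\cdot\lambda_{\max}$; parameter recovery
on $N = 5000$ 1:1 pairs with $p = 50$ binary exposures at prevalence 0.2
and five true effects of $\pm 0.5$, where the mean absolute error of the
true-support coefficients at $\lambda = 0.001\,\lambda_{\max}$ and the
support recovery of 10-fold CV are measured over repeated seeds; and a
capability run fitting a 50-point path on $N = 50{,}000$ strata with
$M = 4$ and $p = 200$ sparse binary predictors through the sparse Gram
formulation. Oracle comparisons use a tighter `kkt_tol` ($10^{-6}$) than
the everyday default, since they compare converged optima rather than
screening fits.

## Known limitations

* Only one case per stratum is supported; K:M designs with several cases
  need the recursive conditional likelihood and are out of scope.
* No standard errors or post-selection inference are produced; the Lasso
  estimates are biased by design and the odds ratios should be read as
  screening quantities.
* For $M > 1$ the solver's convergence is linear, not quadratic; extremely
  tight `kkt_tol` values on very large problems cost proportionally many
  outer iterations.
* The path is computed on a grid; no interpolation between grid points is
  attempted (the conditional-logistic path is not piecewise linear).

## A worked call

```{r example}
d <- simulate_matched(n_strata = 400, n_controls = 1,
                      beta = c(0.9, -0.9, 0, 0, 0, 0),
                      prevalence = 0.25, seed = 42)
cv <- cv_clogit_lasso(d, n_lambda = 30, nfolds = 5, seed = 1)
glance(cv)
tidy(cv$selection)
```
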