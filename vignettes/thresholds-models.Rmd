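---
title: "Thresholds models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thresholds models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irthresh)
```

## The model

For person $p$ and item $i$ with response $Y_{pi}$ on support $S_i$, the
thresholds model states

$$P(Y_{pi} > y \mid \theta_p) = F\big(\alpha_i(\theta_p - \delta_i(y))\big),
\qquad y \in S_i,$$

with a strictly increasing response function $F$ shared by all items, a
discrimination $\alpha_i > 0$, and a non-decreasing item difficulty
function $\delta_i$.  Together with conditional independence of items given
$\theta_p$ and a normal latent distribution
$\theta_p \sim N(0, \sigma_\theta^2)$, this fully specifies the joint
distribution of any mixture of binary, ordinal, count and continuous items.
Because $F$ and $\delta_i$ are monotone, the model is latently monotone:
$P(Y > y)$ never decreases in $\theta$.

The threshold $y$ lives on the observable response scale.  The distribution
function of a response is $F_{pi}(y) = 1 - F(\alpha_i(\theta_p -
\delta_i(y)))$; differencing gives the pmf of discrete items and
differentiating gives the density
$f(\alpha_i(\theta_p-\delta_i(y)))\,\alpha_i\,\delta_i'(y)$ of continuous
ones.  Two closed-form special cases are used as exact regression tests: a
normal $F$ with linear difficulty $\delta(y) = \delta_0 + \delta y$ makes
$Y$ normal with mean $(\theta-\delta_0)/\delta$ and SD $1/(\alpha\delta)$,
and a normal $F$ with $\delta(y) = \delta_0 + \delta\log y$ makes $Y$
log-normal.

**Moment constants.**  With a linear difficulty,
$E(Y) = \gamma\theta - \gamma_0$ and
$\mathrm{var}(Y) = c\,\gamma^2/\alpha^2$ with $\gamma = 1/\delta$ and
$\gamma_0 = (\delta_0 + d/\alpha)/\delta$.  Writing
$Y = (\theta - V/\alpha - \delta_0)/\delta$ with $V \sim F$ shows that $d$
and $c$ are simply the mean and variance of $F$; the package computes them
at construction by adaptive quadrature ($d = 0$ for the two shipped
symmetric response functions; $c = 1$ for the normal, $\pi^2/3$ for the
logistic).  This numeric definition is validated in the tests against
Monte-Carlo moments of simulated responses.

## Difficulty families

| family | $g(y)$ | support | notes |
|---|---|---|---|
| `linear` | $y$ | real, ordinal | normal responses / constant threshold spacing |
| `log` | $\log y$ | positive (counts) | log-normal responses |
| `log1p` | $\log(1+y)$ | count, ordinal | keeps $0$ in the support |
| `adapted_logit` | $\log\frac{1+y}{k-y}$ | ordinal $\{0..k\}$ | symmetric around $(k-1)/2$ |
| `inverse_cdf` | $aF^{-1}\!\big(\tfrac{y-a_0}{b_0-a_0}\big)$ | interval $(a_0,b_0)$ | $a = 1$ by default, configurable |
| `free_ordinal` | — | ordinal | one free threshold per category (graded response) |
| `bspline` | — | any | monotone cubic B-splines, default 6 basis functions |

Parametric families are $\delta(y) = \delta_0 + \delta\,g(y)$ with
$\delta > 0$.  Conventions: $\delta(-1) = -\infty$ (so $P(Y > -1) = 1$) and
$\delta(k) = +\infty$ at the top of a finite support (so $P(Y > k) = 0$);
these apply to discrete supports only — for a continuous item $y = -1$ is
an ordinary response value.  The top category of a finite ordinal support
is always obtained through $\delta(k) = +\infty$, never through an extra
estimated threshold, which keeps the telescoping pmf summing to one by
construction.

Choices the interface fixes:

* **Ordinal coding.**  Ordinal data are internally coded $0, \dots, k$; a
  1–7 rating scale is shifted to $0$–$6$ (the shift is absorbed by the
  intercept for linear difficulties and recorded in the presets'
  `shift` field).  For the `log1p` family the shift matters and shifting
  to a 0-based support is the documented behaviour.
* **Binary items** store only $\delta(0)$; the shape of $g$ is irrelevant
  because any $\delta_0 + \delta g(0)$ collapses into one constant, so no
  slope parameter exists (and a configured slope is ignored with a
  warning).
* **Bounded responses** in $(a_0, b_0)$ keep their original scale; the
  affine map into $(0,1)$ is part of the inverse-cdf transform, so the
  continuous density needs no external Jacobian.  Responses exactly on the
  boundary have infinite difficulty and are rejected; `squeeze_unit()`
  implements the usual $(y(n-1)+0.5)/n$ compression for such data.
* **B-spline knots** are equally spaced over the observed-response range
  (discrete items: the threshold range $0..k-1$ or $0..\max y$), with
  boundary knots repeated.  Monotonicity is enforced by non-decreasing
  coefficients via an increment reparameterization: the first coefficient
  is free and each further one adds $\exp(u)$, turning the order
  constraint into smooth unconstrained optimization.

## Estimation

The marginal likelihood integrates each person's item-density product over
$\theta$.  The integral is approximated by probabilists' Gauss–Hermite
quadrature **standardized to the current $\sigma_\theta$**
($\theta_q = \sqrt{2}\sigma x_q$, weights $w_q/\sqrt{\pi}$), so the nodes
track the latent scale during optimization and the $\sigma_\theta$ score
flows through $\partial\theta_q/\partial\sigma = \theta_q/\sigma$.  The
default of **61 nodes** was chosen so that doubling the node count changes
fitted log-likelihoods by less than $10^{-6}$ even for mixed-format models
with sharp continuous densities; pure discrete fits are converged from
roughly 41 nodes on.

The score function is analytic.  Every difficulty family is linear in its
natural parameters ($\delta_i(y) = \Phi_i(y)^\top\boldsymbol\delta_i$), so
the per-item basis matrices at the observed responses are precomputed once
and an evaluation of the likelihood or score is a handful of dense
person-by-node matrix operations.  For category probabilities
$F(\eta_{lo}) - F(\eta_{hi})$ the survival form $F(-\eta_{hi}) -
F(-\eta_{lo})$ is used whenever it is larger, which avoids catastrophic
cancellation when both arguments are deep in the upper tail; probabilities
are floored at $10^{-300}$ before logging.

**Identifiability.**  With all $\alpha_i$ fixed at 1, $\sigma_\theta$ is
free.  When discriminations vary, the first item's $\alpha$ stays fixed at
1 and $\sigma_\theta$ remains free; this matches the free-parameter
bookkeeping used for AIC (binary item: 1; parametric item: 2, plus 1 if its
$\alpha$ is free; free-ordinal item: $k$; B-spline item: one per basis
function; plus $\sigma_\theta$; a common slope counts once per family
group).

**Optimization.**  BFGS on the unconstrained parameterization
($\log$ slopes, $\log\alpha$, $\log\sigma_\theta$, ordered increments for
free-ordinal and spline blocks) with the analytic gradient, followed by a
Newton polish that uses a finite-difference Hessian of the analytic score:
BFGS stalls once function-value changes reach floating-point resolution,
while the polish drives the score max-norm far below the convergence
criterion (max $|s| < 10^{-5}$).  Starting values: intercepts from per-item
mean responses mapped through $-F^{-1}$ or $-g$, slopes and discriminations
1, $\sigma_\theta$ 1; free-ordinal and spline starts come from the
empirical exceedance frequencies (isotonized).  Non-convergence is reported
in the `converged` flag, never as an error.

**Covariance.**  The observed information is a central finite difference of
the analytic score with respect to the *natural* parameters, inverted as a
full matrix (not per-item blocks); reported SEs are the square roots of its
diagonal.

**Missing data** are dropped from the person's likelihood product (an MAR
assumption); an item with no observed responses contributes zero score.

**Shape penalty.**  For models in which all items share one B-spline
basis, `lambda > 0` subtracts
$\lambda\sum_{i\ge2}\sum_l[(\delta_{il}-\delta_{i,l-1}) -
(\delta_{i-1,l}-\delta_{i-1,l-1})]^2$.  The penalty runs over *all*
adjacent-coefficient increments, so that in the $\lambda \to \infty$ limit
every pair of items has identical increments — i.e. difficulty functions of
identical shape, differing only by shifts (verified in the tests at
$\lambda = 10^6$, where the across-item increment spread drops below
$10^{-2}$).  $\lambda$ is user-supplied; a cross-validated choice is left
to the user rather than automated.

## Person scoring and information

Given fitted item parameters, the posterior of $\theta$ is the item
density/pmf product times the $N(0,\sigma_\theta^2)$ prior, normalized by
the Gauss–Hermite marginal.  The package generalizes the continuous-only
posterior formula to mixed formats by substituting the pmf for discrete
items — stated explicitly because it is the natural but implicit extension.
EAP and the posterior SD come from quadrature moments; MAP from a
derivative-free one-dimensional search on $\pm6\sigma_\theta$.

Discrete item information is computed from analytic category-probability
derivatives ($\pi_r' = \alpha f(\eta_{r-1}) - \alpha f(\eta_r)$, and
$\pi_r''$ from $f'$), in both the general form
$\sum_r (\pi_r'^2 - \pi_r\pi_r'')/\pi_r$ and the second-derivative-free
finite-category form; their numerical agreement is itself a test of the
algebra.  Count-item sums truncate once the upper-tail mass falls below
$10^{-12}$, absorbing the remainder into the last category.  For continuous
items the observed information has the closed form
$\alpha^2[(f'/f)^2 - f''/f]$, which is constantly $\alpha^2$ under a normal
$F$; the expected information integrates this over the implied response
distribution (a change of variables shows it does not depend on the
difficulty function).

## Differential item functioning

DIF replaces $\theta_p$ by $\theta_p + x_p^\top\gamma_i$ *inside*
$F(\alpha_i(\cdot))$ for the items under test — the covariate effect is
multiplied by $\alpha_i$, matching the model's predictor structure.  Items
are tested one at a time by a likelihood-ratio test on $q$ df against a
shared baseline; `dif_screen()` applies Benjamini–Hochberg across items by
default (the correction method is a free design choice).  Constant
covariate columns are rejected at configuration time because they are
confounded with the intercept, as are collinear covariate sets.

## The synthetic-data generator

Continuous responses are drawn by the inverse construction
$Y = \delta^{-1}(\theta - V/\alpha)$, $V \sim F$, which reproduces the
exceedance probabilities exactly; discrete responses by pmf inversion, with
the count-category walk truncated at cumulative mass $1 - 10^{-12}$.
Presets define the study designs used by the tests and the acceptance
script:

* `person_recovery` — 10 continuous linear items, intercepts
  $-2.25 + (i-1)\,0.5$, slopes $(1,1,1,1,2,2,2,2,3,3)$,
  $\sigma_\theta = 1$, $P = 100$;
* `count` — 5 count items, `log1p` difficulties with varying slopes,
  $\sigma_\theta = 1$, $P = 200$;
* `cognition` — 194 persons × 6 seven-category rating items with linear
  difficulties; the generating intercepts/slopes are published estimates
  for a children's self-regulation rating scale, with item 2 carrying
  discrimination 1.630; **synthetic stand-in**, not the real data;
* `fears` — 200 × 5 seven-category items with `log1p` difficulties at
  published estimates for a political-fears survey; synthetic stand-in;
* `fluency` — 202 × 4 count items emulating one-minute verbal fluency
  tasks, $\sigma_\theta = 1.09$;
* `mixed` — the cognition design with items 1 and 5 collapsed to three
  categories at rating-scale thresholds 4 and 6.

The rating presets need a latent scale that the published tables do not
report; $\sigma_\theta = 1.5$ was fixed once on reliability grounds (with
slopes near 1 it gives per-item reliabilities around $0.7$ and a 6-item
scale reliability around $0.93$, typical of well-behaved rating
instruments), and $1.09$ for the fluency preset is the published value.
What the generator does **not** emulate: rater structure, survey sampling
designs, local dependence, response styles, or any non-normal latent
distribution — so passing recovery tests demonstrate correctness of the
estimator under the model, not robustness to violations of it.

## Study designs in the tests and acceptance script

Problem sizes were chosen to keep the whole suite in a few minutes while
leaving the statistical checks informative: count-item recovery uses 20
replications of the $200 \times 5$ design (coverage of truth within 3
reported SEs, expected $\ge 90\%$); the DIF size check and the LRT null
calibration each use 200 replicates of reduced designs (4 binary items at
$P = 100$ with a binary covariate; 3 three-threshold ordinal items at
$P = 80$), with 15 quadrature nodes — sufficient for these small discrete
models.  The null-calibration check compares the mean LRT statistic with
its $\chi^2_{df}$ expectation within $3\sqrt{2\,df/200}$.

## Numerical choices and degenerate inputs

* Probabilities/densities are floored at $10^{-300}$ inside logs.
* A zero category probability in an information calculation raises an
  error naming the offending category.
* `sigma_theta` near zero degenerates gracefully: the marginal likelihood
  tends to the fixed-$\theta$ ($\theta = 0$) likelihood.
* Equal adjacent B-spline coefficients give a locally flat (non-strict)
  difficulty; the resulting zero density is floored, and the increment
  parameterization keeps the optimizer inside the ordered region.
* Support violations are reported with person and item at data-checking
  time; unknown items, decreasing thresholds, non-positive slopes and
  illegal family/support combinations error at construction.

## Known limitations

* Asymmetric or discrete response functions are not provided; the
  `irt_response` type is open for extension but everything shipped assumes
  symmetry (and uses it for tail-stable probability computations).
* One latent dimension; no multidimensional traits or response-style
  factors.
* DIF selection is item-at-a-time; simultaneous penalized selection across
  all items is out of scope.
* The marginal fit assumes a normal latent distribution; no empirical
  histogram or nonparametric latent option.
* Penalized spline fits report SEs from the penalized observed
  information, which ignores smoothing bias.
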