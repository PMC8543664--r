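---
title: "Model flexibility and the bias-variance trade-off in continuous test norming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model flexibility and the bias-variance trade-off in continuous test norming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normtrade)
```

## The problem

Continuous test norming estimates the distribution of raw test scores as a
smooth function of a continuous predictor -- here, age over the range 5-21
years -- so that a normed score exists at every age instead of only within
discrete age groups. The normed score of interest is the normalized *z*
score: for an observed score $x$ at age $a$,

$$\hat z = \Phi^{-1}\!\big(\hat F(x \mid a)\big),$$

where $\hat F(\cdot \mid a)$ is the estimated conditional score distribution
and $\Phi^{-1}$ the standard-normal quantile function. Percentiles and
normalized IQ scores are monotone transforms of $\hat z$, so conclusions
about $\hat z$ carry over to them.

A norming model has two aspects that can be too strict, about right, or too
flexible relative to the population that generated the normative sample:

* the **transversal model** -- the shape of the conditional distribution at a
  fixed age (normal vs skewed/heavy-tailed, constant vs age-varying spread);
* the **longitudinal model** -- how each distributional parameter changes
  with age (constant, linear, polynomial, spline).

Too strict a model produces *bias* in $\hat z$; too flexible a model inflates
its sampling *variance*. The package provides everything needed to quantify
that trade-off by simulation: distribution machinery, a penalized
distributional-regression fitting engine, factorial population models, and
Monte-Carlo evaluation of bias, variance and RMSE on an age-by-score grid.

## Distributions

The central family is the skew Student *t* (SST): the Fernandez-Steel
two-piece skew *t*, rescaled so that $\mu$ is the *mean* and $\sigma$ the
*standard deviation* of the distribution. Writing $t_\tau$ for the standard
Student-*t* density, the raw two-piece variate $Z$ has density

$$f(z) = \frac{2}{\nu + 1/\nu}\left[\,t_\tau(z/\nu)\,\mathbf 1\{z \ge 0\} +
t_\tau(\nu z)\,\mathbf 1\{z < 0\}\,\right],$$

and the SST variate is $X = \mu + \sigma (Z - \mathbb E Z)/\mathrm{sd}(Z)$,
which requires $\tau > 2$ for the standardization to exist. $\nu > 0$
controls skewness ($\nu = 1$ symmetric, $\nu < 1$ left-skewed) and $\tau$
tail weight; as $\nu \to 1,\ \tau \to \infty$ the SST converges to the
normal. The mean-SD parameterization is what makes the factorial population
design clean: the homoscedastic and normal restrictions act directly on
$\sigma$ and on $(\nu, \tau)$ without changing the meaning of $\mu$. The
cdf and quantile are closed-form (piecewise in $t_\tau$), so density
integration, round-trips and inverse-cdf sampling are exact up to the
`pt`/`qt` primitives; the moment contract ($\mu$ = mean, $\sigma$ = SD) is
verified against quadrature oracles in the test suite rather than trusted
from the algebra.

The Box-Cox Power Exponential (BCPE) distribution is included as the
"different distribution" estimation model: a Box-Cox transform of $x/\mu$
with power $\nu$ is modelled as a standardized power-exponential variate
with kurtosis parameter $\tau$ ($\tau = 2$ is the normal kernel). Its
support is positive, so the estimation model is fitted on scores + 100 and
its quantiles are shifted back; $\mu$ is approximately the conditional
median and $\sigma$ approximately the coefficient of variation. The density
is normalized *exactly* on $(0, \infty)$ -- the truncation induced by the
positivity constraint enters the normalizing constant -- so the quadrature
and round-trip invariants hold to the same tolerances as for the SST.

Default links map each parameter to the real line: identity for $\mu$, log
for $\sigma$; the SST uses $\log \nu$ and $\log(\tau - 2)$, the BCPE an
identity link for $\nu$ and $\log \tau$. The normal family is implemented
exactly (not as a large-$\tau$ SST): the $\tau \to \infty$ limit is a
statement about the population, and estimating a very large $\tau$ from
normal data is precisely the instability the study design avoids building
into its data-generating truth.

## Terms, bases and smoothing

Each distributional parameter is modelled on its link scale as one function
of age: a constant, a straight line, an orthogonal polynomial (QR-based,
with the transform stored for prediction at new ages), or a P-spline.
P-splines use cubic B-splines on equally spaced knots with a second-order
difference penalty, so the penalty null space is the space of straight
lines and $\lambda \to \infty$ shrinks the curve to a line. "6 knots" is
interpreted as **6 interior knots** (basis dimension 10); this follows
common P-spline practice, though conventions differ and the knot count is a
configurable argument, not a constant. Ages outside the knot range are
evaluated by clamping to the boundary -- the evaluation grid coincides with
the sampling range, so this only guards edge rounding.

A single smoothing parameter per term is selected by GAIC with penalty
$k = 5$ by default ($k = \log n$ gives BIC-selected smoothing, $k = 0.1$
the deliberately overflexible variant used in the diagnostics
illustration).

## The fitting engine

`fit_norm()` maximizes the penalized log-likelihood
$\ell(\beta) - \tfrac12 \sum_k \lambda_k \beta_k^\top P_k \beta_k$
by outer backfitting: each parameter's coefficients are updated in turn by
penalized iteratively reweighted least squares, holding the others fixed,
with the score $u_i = \partial \ell_i / \partial \eta_i$ and curvature
$w_i = -\partial^2 \ell_i / \partial \eta_i^2$ of the pointwise
log-likelihood with respect to that parameter's linear predictor. For the
normal family these derivatives are closed-form (and the intercept-only fit
reproduces closed-form maximum likelihood to near machine precision); for
the SST and BCPE they are central differences with step $10^{-3}$ on the
link scale, which is accurate far beyond what the weak identification of
$\nu$ and $\tau$ at realistic sample sizes can exploit. Nonpositive
curvatures (the pointwise likelihood need not be concave) are floored at a
small positive multiple of the median curvature, and each update is
step-halved until the penalized deviance does not increase.

Numerical choices, all recorded as defaults rather than constants:

* **Initialization**: $\mu$ from (penalized) least squares on the scores,
  $\sigma$ from the residual SD, $\nu$ and $\tau$ at neutral values
  ($\nu = 1$; SST $\tau = 3$, BCPE $\tau = 2$, the normal kernel). If the
  likelihood is not finite at the start, $\sigma$ is inflated until it is.
* **Convergence**: absolute change in global deviance between outer cycles
  below `tolerance` (default $10^{-3}$, mirroring common practice in
  distributional-regression software). A fit that hits `max_iterations`
  (default 2000 outer cycles) is returned usable with `converged = FALSE`
  and counted as type-2 nonconvergence; outright numerical breakdown (or
  more coefficients than observations) yields `failed = TRUE`, type-1, with
  no coefficients.
* **Smoothing selection**: an `"auto"` $\lambda$ is profiled inside each
  IRLS update by minimizing the GAIC of the *weighted working model* over
  $\log \lambda \in [\log 10^{-4}, \log 10^{6}]$. This is re-done each
  cycle while the weights are settling and frozen after 15 cycles so the
  fixed-penalty backfit converges monotonically. Ties prefer the smoother
  end. The refit-based `select_lambda()` (golden section on the full-model
  GAIC) is the explicit counterpart used when a reproducible, profile-exact
  selection is wanted; both minimize the same criterion.
* **Link-scale guards**: linear predictors of exponential links are clamped
  to $\pm 30$ before inversion so overflow cannot occur; the identity link
  is never clamped.
* **Effective degrees of freedom**: per parameter,
  $\mathrm{tr}\big((X^\top W X + \lambda P)^{-1} X^\top W X\big)$ at the
  converged weights; unpenalized terms contribute their column count.

The BIC model search (`select_model_bic()`) fits a candidate list and
returns the lowest-BIC fit, breaking ties by smaller total edf and then
candidate order; `sst_poly_candidates()` enumerates the full
$6 \times 6 \times 6 \times 3 = 648$ polynomial SST grid (degrees 0-5 for
$\mu, \sigma, \nu$; 0-2 for $\tau$) from which such a flexible reference
model is chosen.

## The population cube

The data-generating truths form a $2^3$ factorial over three restrictions
of a fully flexible model: linearity of the mean, homoscedasticity, and
normality. The flexible curves ship as an explicit, documented coefficient
set on the link scale, polynomial in the rescaled age $t = (a - 13)/8$,
with the degrees of the flexible structure (4 for $\mu$ and $\log \nu$, 2
for $\log \sigma$, 1 for $\log(\tau - 2)$):

```{r curves}
str(build_population()$curves)
population_params(build_population(), c(5, 13, 21))
```

They emulate a developmental ability test: the mean rises steeply in
childhood (about 9 points at age 5 to 34 at age 21) and decelerates toward
adulthood; the SD grows mildly from about 3.4 to 4.9; scores are
left-skewed ($\nu \approx 0.6$-$0.7$); tails are moderately heavy
($\tau \approx 5$-$7$). No published coefficient set exists for such
populations, so these values are a design choice of this package, made once;
every quantitative result the package reports is defined relative to
whatever population configuration is active, and the curves are fully
user-overridable via `build_population(curves = ...)`.

The restricted variants are derived, not hand-set: the linear-$\mu$ variant
is the least-squares line through the flexible mean curve over the age
range, the homoscedastic variant fixes $\sigma$ at its age-average, and the
normal variant switches to the exact normal family. Ages in a normative
sample are `n` evenly spaced values spanning the age range -- a design
choice of the study layout, not random -- and scores are drawn by
inverse-cdf sampling, so a single uniform stream drives every family.

## Outcome measures

`build_grid()` lays out $I$ equally spaced ages (default 1000) and $J$
equally spaced population z values on $[-3, 3]$ (default 100; scores more
extreme than three population SDs are excluded because such normed scores
are not reported in practice). For each grid cell $(i, j)$, each replicate
yields a clamped estimate $\hat z_{ijr}$, and across $R$ replicates

$$\mathrm{bias}_{ij} = \bar{\hat z}_{ij} - z_{ij}, \qquad
\mathrm{variance}_{ij} = \tfrac1R \sum_r (\hat z_{ijr} - \bar{\hat z}_{ij})^2, \qquad
\mathrm{RMSE}_{ij} = \sqrt{\tfrac1R \sum_r (\hat z_{ijr} - z_{ij})^2},$$

all with $1/R$ normalization, so $\mathrm{RMSE}^2 =
\mathrm{variance} + \mathrm{bias}^2$ holds as an identity (and is asserted
to $10^{-12}$ in the tests). Estimated percentiles are clipped to
$[10^{-15}, 1 - 10^{-15}]$ before $\Phi^{-1}$ and the resulting z scores
bounded to $[-5, 5]$: tiny differences in extreme estimated percentiles
otherwise explode into infinite $\hat z$. The clamp is part of the
estimator, so all downstream aggregation uses the clamped values.
Condition-level summaries are unweighted means over the grid of
$|\mathrm{bias}|$, variance and RMSE. Replicates whose fit failed outright
are excluded; fits stopped at the iteration cap are included.

## The factorial study

`enumerate_conditions()` crosses the eight populations with the estimation
models applicable to each: the true model (family and term structure
mirroring the population) and the BCPE model always; the polynomial true
model only for the fully flexible population; strict variants only where
there is structure to restrict; flexible variants only where there is a
restriction to relax. This yields 43 population-by-estimation combinations
and 129 conditions over the three sample sizes (500, 1000, 2000), with
$8 \times 3 \times R$ generated samples (24,000 at $R = 1000$); each sample
is shared by all estimation models fitted to it (common random numbers),
which removes between-model Monte-Carlo noise from the comparisons.

The study's flexibility classes fix only part of the term structure
explicitly (linear vs spline mean; normal-homoscedastic vs skew-*t*
transversal). Where the structure of the true and flexible models beyond
the mean is not pinned down, the package mirrors the population per
parameter -- intercepts for constant parameters, P-splines for age-varying
ones -- on the grounds that the "true" model should track the structure it
is named after; the flexible transversal variant uses P-splines for
$\sigma$, $\nu$ and $\tau$ regardless. Per-replicate seeds come from a
counter-based splitter of the master seed, so results are identical no
matter which subset of conditions is run.

At full scale the study is a cluster-sized computation. The test suite and
the acceptance script run a reduced configuration -- $R = 100$ replicates,
$n = 500$ (plus $n = 2000$ for the true model), a $100 \times 50$ grid,
and the two extreme populations (fully flexible `NL-HeNN` and fully
restricted `Li-HoNo`) -- chosen as the smallest design that still separates
the flexibility classes cleanly. At that scale the expected orderings are
unambiguous: the doubly strict model carries more bias than either singly
strict model; every flexible model carries at least the true model's
variance; the true model's RMSE beats the doubly strict model's; and the
true model's variance shrinks from $n = 500$ to $n = 2000$. The per-cell
RMSE heat map for the most restricted population under the most flexible
estimation model concentrates its large values below population
$z \approx -2.7$: the skew-*t* estimated on normal data misplaces the
extreme lower tail while the P-splines track age consistently.

## Diagnostics

In practice the population model is unknown, so under- and overfitting must
be diagnosed from the sample. `quantile_residuals()` computes
$\Phi^{-1}(\hat F(x_k \mid a_k))$ -- standard normal under a correct model
(scores are continuous, so no randomization is needed) -- and
`worm_plot_data()` detrends their Q-Q plot within equal-count age bins
(default 4). `fit_three_way()` contrasts a deliberately strict fit
(normal, linear mean, constant spread), a properly smoothed SST P-spline
fit with BIC-selected $\lambda$, and an overflexible GAIC(0.1) fit: the
strict fit's worms bow far from zero (underfit is best seen in worm
plots), while the GAIC(0.1) fit spends several times the effective df and
produces visibly wiggly centiles (overfit is best seen in centile curves
against theoretical expectations of smoothness).

## What the synthetic data does and does not show

The generator reproduces the structural features the study manipulates:
smooth polynomial age dynamics in all four distributional parameters,
skewness, heavy tails, heteroscedasticity, and their restricted
counterparts. It does not emulate features of real normative data such as
discreteness or bounded score ranges, floor/ceiling effects, bimodality,
non-uniform age sampling, additional predictors (sex, education), or
measurement non-invariance. Passing the qualitative orderings here
therefore says the estimators and the evaluation pipeline behave correctly
under the stated population classes -- not that any particular empirical
test behaves like these populations.

## Known limitations

* One predictor (age); no tensor-product or multi-predictor smooths.
* Continuous families only; discrete or ordered-categorical scores are out
  of scope.
* The SST's $\tau$ is weakly identified on (near-)normal data; expect
  iteration-cap fits there. That behavior is informative -- it is the reason
  the BCPE is often the safer default in practice -- and such fits are
  retained in the evaluation rather than discarded.
* Monte-Carlo standard errors are reported for the mean-squared-error
  aggregate via across-replicate variation of the per-replicate grid mean;
  the aggregate of per-cell RMSE is a nonlinear functional, so its SE is
  only approximate.
* Confidence intervals for raw scores, semiparametric norming alternatives
  and IRT-based measurement models are deliberately outside the package's
  scope.
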