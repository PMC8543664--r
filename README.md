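# normtrade

Bias–variance trade-off in continuous test norming.

`normtrade` is a simulation laboratory for psychometricians and
biostatisticians who build **continuous norms**: models of a test-score
distribution as a smooth function of age, from which a normed score exists
at every age. Its question is how the *flexibility* of the norming model —
in the conditional distribution's shape (transversal) and in how its
parameters move with age (longitudinal) — trades **bias** against
**variance** in the estimated normalized *z* scores.

## The model

A normative sample of `(age, score)` pairs is fitted by distributional
regression (GAMLSS-style): each parameter of a response family gets its own
function of age on a link scale,

```
score | age  ~  D(mu(age), sigma(age), nu(age), tau(age))
```

with `D` the skew Student *t* (SST; mean–SD parameterized, `nu` skewness,
`tau > 2` tail weight, normal at `nu = 1, tau = Inf`), the Box–Cox Power
Exponential (BCPE, fitted on scores + 100), or the normal. Age functions
are constants, lines, orthogonal polynomials, or P-splines (cubic
B-splines, 6 interior knots, second-order difference penalty) with the
smoothing parameter chosen by GAIC (penalty 5 by default; `log n` gives
BIC). The normed score of an observed `x` at age `a` is

```
z_hat = qnorm( F_hat(x | a) ),   bounded to [-5, 5]
```

Monte-Carlo evaluation draws `R` normative samples from a known population,
fits an estimation model to each, and measures per cell of an age × score
grid (ages on [5, 21], population z on [−3, 3]):

```
bias_ij     = mean_r(z_hat_ijr) - z_ij
variance_ij = mean_r( (z_hat_ijr - mean_r z_hat_ij)^2 )
RMSE_ij     = sqrt( mean_r( (z_hat_ijr - z_ij)^2 ) )      # RMSE² = variance + bias²
```

Populations form a 2³ factorial cube — {nonlinear/linear mean} ×
{hetero/homoscedastic} × {nonnormal/normal} — and each is attacked by the
estimation models applicable to it (true, strict and flexible variants in
both aspects, plus BCPE): 43 population × model combinations, 129
conditions over sample sizes 500/1000/2000.

## Worked example

Fit the true model to one normative sample from the fully flexible
population and norm some scores:

```r
library(normtrade)

pop <- build_population()          # fully flexible population (NL-HeNN)
d   <- sample_norm_data(pop, n = 500, seed = 42)

fit <- fit_norm(d, build_estimation_spec(pop, "True[linear/splines]"))
glance(fit)
#> # A tibble: 1 × 9
#>   logLik deviance   edf   AIC   BIC iterations converged failed  nobs
#>    <dbl>    <dbl> <dbl> <dbl> <dbl>      <int> <lgl>     <lgl>  <int>
#> 1 -1413.    2826.  8.97 2844. 2881.         50 TRUE      FALSE    500

predict_params(fit, c(6, 13, 20))
#> # A tibble: 3 × 5
#>     age    mu sigma    nu   tau
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     6  11.8  4.49 0.550  3.20
#> 2    13  23.3  4.63 0.666  5.70
#> 3    20  32.5  4.77 0.806 13.4

estimate_z(fit, tibble::tibble(age = c(8, 8, 16), score = c(10, 22, 35)))
#> # A tibble: 3 × 5
#>     age score percentile     z clamped
#>   <dbl> <dbl>      <dbl> <dbl> <lgl>
#> 1     8    10     0.0934 -1.32 FALSE
#> 2     8    22     0.988   2.25 FALSE
#> 3    16    35     0.972   1.91 FALSE
```

The fitted mean rises from ~12 to ~33 over the age range while skewness and
tail weight vary with age; a score of 10 at age 8 sits 1.3 population SDs
below the age norm. Centile tables (`centile_curves()`) and worm-plot data
(`worm_plot_data()`) have `autoplot()` methods.

A miniature of the simulation itself — the true model versus the doubly
strict model (normal, linear mean, constant spread) on the same population:

```r
st <- run_study(populations = pop, sample_sizes = 500, R = 20, I = 50, J = 25,
                seed = 1, models = c("True[linear/splines]", "Strict[long,trans]"))
st$aggregates[, c("model", "n", "mean_abs_bias", "mean_variance", "mean_rmse")]
#> # A tibble: 2 × 5
#>   model                    n mean_abs_bias mean_variance mean_rmse
#>   <chr>                <dbl>         <dbl>         <dbl>     <dbl>
#> 1 True[linear/splines]   500        0.0554        0.0463     0.191
#> 2 Strict[long,trans]     500        0.425         0.0314     0.470
```

The strict model buys a little variance (0.031 vs 0.046) at the cost of
eight times the bias (0.425 vs 0.055), and loses decisively on RMSE — the
trade-off the package exists to measure.

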