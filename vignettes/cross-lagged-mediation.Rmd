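---
title: "Longitudinal mediation with autoregressive cross-lagged models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal mediation with autoregressive cross-lagged models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpmed)
```

## The problem

Occupational cohort surveys measure psychosocial work characteristics
(demands and social support from the Demand-Control Questionnaire),
health behaviors (smoking, excessive drinking, diet, physical activity)
and depressive symptoms (the six-item SCL-CD6 subscale) repeatedly, every
couple of years. A natural question is whether unhealthy behaviors act as
*intermediaries*: does low support raise depressive symptoms partly
because it first pushes people toward, say, excessive drinking?

With at least three measurement waves the temporal ordering of exposure,
mediator and outcome can be represented explicitly. `clpmed` implements
the autoregressive cross-lagged approach to that question: each construct
at wave $t{+}1$ is regressed on itself and on the other constructs at
wave $t$, so every cross-lagged coefficient is adjusted for the outcome's
own stability, and reverse-direction paths are estimated rather than
assumed away.

## Model

For constructs $X$ (work characteristic), $M$ (behavior propensity) and
$Y$ (depressive symptoms) at waves $t = 1, \dots, T$ (default $T = 4$),
the structural part is the lag-1 system

$$\eta_{t+1} = B_t \, \eta_t + \zeta_{t+1}, \qquad
  \eta_t = (X_t, M_t, Y_t)',$$

with all lag-1 paths (autoregressive and cross-lagged, both directions)
freed per transition, and within-wave covariances among the wave-1
constructs and among the innovations at later waves. Time-constant
versions of the structural paths can be imposed as equality constraints
and compared by a chi-square difference test (`nested_test()`); in the
motivating application that comparison favored time-varying paths, which
is why per-transition coefficients are the default.

Measurement: demands (4 items), support (5 items) and depressive
symptoms (6 items) are latent variables with ordinal indicators; the
first loading is fixed to 1 for identification and loadings are
constrained equal over waves by default (`equal_loadings = TRUE`),
reflecting measurement invariance. Same-item errors are allowed to
covary across waves with a single lag-invariant parameter per item,
absorbing consistent item-specific variance. A dichotomous behavior
enters through the latent response formulation: the observed 0/1
indicator is a thresholded standard-normal latent response whose total
variance is fixed at 1 (delta parameterization), and that latent
response is itself the structural $M$ node.

## Estimation routes

Two deliberately distinct routes are provided, because a
categorical-faithful weighted least squares fit and full-information
likelihood handling of missing data do not combine into a single
estimator here:

* `estimator = "wls"` (reference route): two-stage estimation. Stage 1
  computes item thresholds from univariate margins and a
  polychoric/polyserial/tetrachoric correlation matrix from
  pairwise-present observations, each correlation by maximum likelihood
  with the bivariate-normal CDF evaluated by 48-node Gauss-Legendre
  quadrature. Stage 2 minimizes the diagonally weighted least-squares
  discrepancy between those correlations and the model-implied ones,
  with weights equal to the inverse asymptotic variances obtained from
  the curvature of each pairwise likelihood. Parameter covariance uses
  the standard DWLS expression with the asymptotic covariance of the
  correlation vector approximated as diagonal; with that approximation
  the sandwich form collapses to the naive $({\Delta}'W\Delta)^{-1}$,
  which is what `fit_sem()` reports. Consequences: p-values on wls
  structural paths are approximate, and the replicated calibration
  studies below therefore run on the maximum-likelihood route, whose
  standard errors are exact for the recursive system.
* `estimator = "ml"`: normal-theory maximum likelihood treating
  variables as continuous, on complete cases or with
  `missing = "fiml"`, which evaluates the exact observed-data Gaussian
  likelihood pattern by pattern (the saturated log-likelihood needed for
  the chi-square is obtained by an EM algorithm).

Model fit is summarized by the usual chi-square statistics and

$$\mathrm{CFI} = 1 - \frac{\max(\chi^2_m - df_m, 0)}
  {\max(\chi^2_m - df_m,\ \chi^2_0 - df_0,\ 0)}, \qquad
  \mathrm{RMSEA} = \sqrt{\frac{\max(\chi^2_m - df_m, 0)}{df_m (n-1)}}.$$

Optimization is quasi-Newton (`nlminb`) on flat index-compiled model
matrices, with lower bounds on variance parameters, convergence at a
relative objective change below $10^{-9}$ (a finite-difference gradient
norm below $10^{-4}$ is also accepted), and up to three seeded, jittered
restarts; non-convergence is reported with the gradient norm and
iteration count. Ordinal residual variances are never free parameters:
they are solved from the linear system that keeps every ordinal latent
response at unit total variance, so Heywood-style negative residuals
surface as errors instead of silently wandering.

## Screening, gating, and the effect calculus

Mirroring the staged analysis design, bivariate two-construct models are
fitted first (`fit_bivariate()`), and a mediation model for a behavior
is fitted only when at least one exposure-to-behavior path *and* at
least one behavior-to-outcome path is significant at $\alpha = 0.05$
(`gate_mediation()`). The threshold is per path and two-sided, with no
multiplicity correction -- deliberately liberal screening, which should
be kept in mind when interpreting gate decisions. Reverse paths are
always reported, never gated on.

For a fitted three-construct model, the overall effect of $X_1$ on
$Y_T$ decomposes by the product-of-coefficients method over the forward
lag-1 edge set $\{X{\to}X, X{\to}M, X{\to}Y, M{\to}M, M{\to}Y,
Y{\to}Y\}$:

* *indirect* = sum over all forward paths visiting an $M$ node of the
  product of standardized coefficients along the path;
* *direct* = the same sum over paths avoiding $M$;
* *total* = direct + indirect (an exact identity, preserved draw by
  draw in the Monte Carlo step);
* *proportion mediated* = indirect / total, reported as interpretable
  only when the total's interval excludes zero.

`enumerate_paths()` lists the paths explicitly (for $T = 4$ there are
six, three of each kind), and the package's tests verify the path-sum
against an independent matrix-product oracle, $\big[\prod_t
B_t\big]_{YX}$, to $10^{-12}$ over random systems with $T \in \{2,
\dots, 5\}$.

Standardized coefficients are used throughout the calculus, the
recommended scale when mediators are dichotomous. Reverse and
within-wave edges, although estimated, are excluded from the products;
and all effects run from the exposure at analysis wave 1 to the outcome
at analysis wave $T$. (The source analysis indexes its waves 2-5 of the
parent cohort but once describes the same span as "wave one to wave
four"; this package fixes the convention to analysis waves 1 to $T$ and
leaves the cosmetic discrepancy alone.)

## Monte Carlo confidence intervals

Uncertainty for the nonlinear effect functions comes from simulating
20,000 coefficient vectors from a multivariate normal centered at the
structural estimates with their estimated covariance, recomputing the
three effects per draw, and taking percentile intervals (bias-corrected
variants are not used; the percentile form is the standard one for this
interval). Draws are taken over structural coefficients only --
measurement parameters are held fixed -- and on the standardized scale,
using the delta-method covariance of the standardized coefficients. An
effect is flagged significant when its interval excludes zero. Draws are
deterministic given the seed.

## The synthetic cohort generator

No individual-level data from the motivating survey are distributable,
so `sim_config()`/`generate_panel()` define the study conditions the
package is tested under. The generator is the exact model the analysis
assumes -- a standardized lag-1 latent system with probit-linked ordinal
items -- plus known true parameters, so every estimation stage has a
parameter-recovery oracle (`true_effects()` applies the same path
calculus to the generating coefficients).

Choices worth knowing:

* **Unit-variance bookkeeping.** Innovation variances are derived so
  every latent stays at variance 1 at every wave; thresholds are then
  standard-normal quantiles at all waves, and behavior prevalences are
  wave-constant, matching the observation that roughly the same
  proportion was classified as excessive drinkers in every wave. Wave-1
  correlations come from the fixed point of the standardized recursion.
* **Calibration.** Default behavior thresholds reproduce the baseline
  descriptives: smoking 8.3%, excessive alcohol 5.2%, unhealthy diet
  6.8%, inactivity 16.1%. Item cutpoints are chosen so composite means
  match: demand items at `qnorm(c(.12, .45, .83))` give an expected
  item mean of $1 + .88 + .55 + .17 = 2.6$; support items at
  `qnorm(c(.05, .20, .65))` give 3.1; depressive items at
  `qnorm(c(.55, .75, .85, .95))` give 0.9 per item, hence 5.4 on the
  0-24 sum. Default AR coefficients (0.55-0.6) and loadings (0.65-0.8)
  are ordinary magnitudes for two-year panel stability and
  questionnaire measurement in this field.
* **Missingness.** MCAR masks cells independently; MAR masks wave-2+
  cells with logistic probability in the observed wave-1 depressive
  score (ignorable given observed data). The motivating paper does not
  report its missingness pattern, so rates are free parameters; the
  realistic default used in examples is 5% MCAR.
* **Raw behavior items.** With `emit_raw_items = TRUE` the generator
  emits smoking status, AUDIT weekly units and binge flags (waves 1-2),
  CAGE items (waves 3-4), diet category and exercise frequency,
  constructed to be exactly consistent with the binary indicators so
  the scoring rules in `derive_variables()` round-trip.
* **What it does not emulate.** Real panels have informative
  whole-person dropout, non-normal latent dynamics, time-varying
  covariates, measurement non-invariance and misspecified structure.
  Passing recovery tests on this generator shows the estimators are
  correct under the model's own assumptions -- not that the assumptions
  hold in any particular survey.

## Scoring rules

`derive_variables()` implements the questionnaire conventions: demand
and support composites as the mean of items on the 1-4 scale (missing
when more than half the items are missing -- the source is silent here,
so the fraction is configurable); the depressive sum 0-24 (missing if
any item is missing, with a configurable prorating option); daily
smoking versus other (sensitivity: any smoking); excessive drinking by
AUDIT consumption items in the first two analysis waves (men 21+ or
women 14+ units weekly, or 6+ units per occasion at least weekly) and
by CAGE (2+ of 4 items) afterwards -- the instrument changed between
the first two waves, and which instrument the final wave used is not
documented, so the per-wave mapping is a configurable rule defaulting
to CAGE from wave 3 on; one unhealthy-diet category versus three
healthy ones; inactivity as exercising very little or never
(sensitivity: adding "now and then"); and the 0-4 unhealthy-behavior
count.

## Problem sizes used in the tests

The replicated calibration studies run on the observed-variable route:
interval coverage and null calibration use 500 replications of $n =
500$ panels with 20,000 Monte Carlo draws each; coefficient recovery
uses 50 replications at $n = 2000$ (the latent wls route is verified
for bias at 10 replications of $n = 2000$, and pointwise on single
larger fits). These sizes give binomial Monte Carlo error around 1
percentage point on coverage while keeping the whole suite comfortably
reproducible on a laptop.

## Known limitations

* The wls route's standard errors rest on the diagonal approximation to
  the correlation-vector covariance described above; mean-and-variance
  scaled test statistics are not implemented.
* FIML is available for continuous-coded data only; categorical
  full-information likelihood (numerical integration over latent
  responses) is out of scope, as are multiple-group models and formal
  longitudinal measurement-invariance testing.
* Counterfactual (natural or interventional) effect definitions and
  exposure-mediator interactions are out of scope; the decomposition
  here is the classical product-of-coefficients one, whose causal
  reading requires the usual no-unmeasured-confounding and
  no-interaction assumptions.
* Proportion mediated is numerically unstable when the total effect is
  near zero; it is reported but flagged not interpretable unless the
  total's interval excludes zero.

## A compact worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_subjects = 2500, seed = 103,
  crosslag = matrix(c(0, 0, 0,
                      0.35, 0, 0,
                      0.10, 0.35, 0), 3, 3, byrow = TRUE),
  emit_raw_items = TRUE
)
true_effects(cfg)

run <- run_pipeline(run_config(
  cfg, exposure = "support", mediators = "alcohol",
  engine = "composite", seed = 2
))
run$mediation_table
```

The composite engine treats scale scores and indicators as observed
variables -- fast, and attenuated by measurement error relative to the
latent truth; `engine = "sem"` fits the full latent/ordinal model and
recovers the generating effects up to sampling error, at a few dozen
seconds per model.
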