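---
title: "Prey-depletion functional responses: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prey-depletion functional responses: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcresp)
library(dplyr)
```

## The problem

A functional-response experiment offers a single predator a range of prey
densities for a fixed exposure and counts how many prey are gone at the end.
The shape of consumption against density separates a hyperbolic (type II)
response — constant attack rate, saturating only through handling time —
from a sigmoidal (type III) response, in which the attack rate itself
accelerates with prey density. The distinction matters because type III
responses give prey a low-density refuge and stabilize predator-prey
dynamics, while type II responses do not.

funcresp implements the complete inference chain for such experiments with
nematode-scale organisms in mind: closed vials, no prey replacement, a
4-hour exposure, predator-free control vials used to correct the nominal
densities, two prey size classes, and an optional structured substrate.

## Models

Because eaten prey are not replaced, the density a predator experiences
falls during the trial. Integrating the Holling disc consumption rate
$dN/dt = -aN/(1 + ahN)$ over the exposure $T$ gives the random-predator
(Rogers) equation, an implicit relation for the number eaten $N_e$ from an
initial count $N_0$:

$$N_e = N_0\left[1 - e^{a(N_e h - T)}\right],$$

with attack rate $a$ and handling time $h$. `fr_predict_typeII()` evaluates
its closed-form solution through the principal branch of the Lambert-W
function,

$$N_e = N_0 - \frac{W_0\!\big(a h N_0\, e^{-a(T - hN_0)}\big)}{a h},$$

and `fr_predict_flexible()` generalizes the attack rate to a power law of
the initial density, $a_{\mathrm{eff}} = b N_0^{\,q}$, held fixed within a
trial. At $q = 0$ the flexible model reduces exactly to type II; $q > 0$
produces sigmoidal responses. The scaling exponent is applied to the
*initial* density, not the instantaneous one — conventions differ across
the literature, so the package states its choice explicitly.

Three independent routes to the same number guard the implementation: the
Lambert-W closed form, bisection on the implicit residual
(`fr_implicit_residual()`, also the fallback when the exponential
overflows), and direct ODE integration of the disc equation
(`fr_ode_eaten()`). The test suite holds them to within $10^{-8}$ and
$10^{-6}$ prey of one another over the full design grid.

```{r models}
fr_predict_typeII(300, time = 1 / 6, a = 2.686, h = 0.024)
fr_predict_flexible(c(5, 50, 300), time = 1 / 6, b = 0.173, q = 0.739,
                    h = 0.003)
```

## Units

The package carries a single consistent time unit: rates are per unit time
and handling times in time, so any choice works if used consistently. The
defaults use **days** — a 4-hour exposure is `exposure_time = 1/6` — because
that is the unit in which the canonical parameter magnitudes bundled in
`fr_default_truth()` (search coefficients around 0.2–0.8, handling times of
a few 10⁻³, scaling exponents 0.36–0.74) reproduce realistic trial
outcomes: a few tens of prey eaten at the highest densities rather than
total consumption everywhere. Expressed per hour the same magnitudes would
imply essentially complete depletion at every density within 4 h, which no
feeding trial of this kind shows; treating them as per-day rates is the
only reading under which model, parameters and observed consumption levels
cohere.

## Preprocessing

`fr_prepare_trials()` implements the control-based correction: the
corrected initial density of a treatment-by-density cell is the mean final
count of its predator-free controls, rounded half-to-even so the binomial
likelihood keeps an integer index (the rounding rule is this package's
choice; fractional corrected densities would require a quasi-likelihood).
Prey eaten is corrected initial minus final count, clamped below at zero —
counting noise can leave a predator vial richer than the control mean — and
above at the corrected initial, symmetrically. Clamps are reported as
messages; control vials are consumed by the step. A predator vial with no
matching controls is an error, and all-zero controls yield a zero corrected
density with a warning rather than a division artifact.

## Likelihood and fitting

The observation model is binomial: each vial contributes
$N_e^{\mathrm{obs}} \sim \mathrm{Binomial}(N_0,\; N_e^{\mathrm{pred}}/N_0)$,
with the predicted proportion clipped to $[10^{-9}, 1-10^{-9}]$. Published
analyses of this class of experiment rarely state a likelihood explicitly;
the binomial is the convention of the maximum-likelihood fitting frameworks
the field uses, it respects the $[0, N_0]$ support of the counts, and it
makes Wald standard errors well defined.

`fr_fit()` maximizes this likelihood with Nelder-Mead over log-transformed
positive parameters ($a$, $b$, $h$) and raw $q$ (constrained to
$q > -1$ by penalty). Starts come from a Holling-disc moment heuristic —
attack rate from inverting exponential depletion at the three lowest
densities, handling time from the reciprocal high-density asymptote,
$q_0 = 0.5$ midway through the plausible range — plus seeded jitter for the
remaining restarts (default 5). Standard errors are delta-method transforms
of the inverse numerically differentiated Hessian on the fitting scale; a
non-invertible Hessian marks the fit `converged = FALSE` rather than
erroring, and fully degenerate data (nothing eaten anywhere) short-circuit
with a message. Two fits with the same data and seed are identical.

Model choice uses AICc, $-2\ell + 2k + 2k(k+1)/(n-k-1)$; ties and
non-convergence resolve toward the simpler type II model. A flexible fit is
called type III only when $\hat q > 0$ *and* its two-sided Wald test
against zero is significant — two-sided because that is what reproduces the
printed p-values of published analyses in this area, even though the
scientific hypothesis is one-sided.

## Shape diagnostics

`fr_shape_test()` fits the classical polynomial logistic regression of
proportion consumed on raw powers of density (degree 1 or 2) via
`stats::glm`. Raw rather than orthogonal polynomials keep the signed,
interpretable first- and second-order terms the field reports; degree is
capped at 2. A significant negative linear term is the type II signature; a
significant positive-then-negative quadratic pair is the type III
signature; `fr_classify_shape()` reports both when both fire (strongly
sigmoidal data commonly show both) and leaves the final call to AICc. The
diagnostic is advisory — it describes the curve's shape, not a mechanistic
model.

## Uncertainty

`fr_bootstrap()` resamples vials (rows) with replacement to the original
sample size and refits each resample from the original optimum, dropping
and counting non-converged replicates so the requested size is an upper
bound. The default resamples rows freely, the framework convention; a
`stratify` option resamples within density levels instead, which the
balanced design makes natural — both are provided because published
analyses rarely say which they used. Percentile 2.5/97.5 intervals come
from the converged replicates, and `fr_curve_band()` propagates the
replicate parameter sets into a pointwise 95% band around the fitted curve.

`fr_compare_treatments()` asks whether a parameter differs between two
treatments by fitting a single pooled likelihood in which group B's
parameters are group A's plus difference terms, then Wald-testing each
difference — the difference-parameterization approach standard in this
area, chosen over bootstrap-difference percentiles because it yields the
bare p-values that published comparison tables report. Finite-difference
steps for the pooled Hessian are scaled per coordinate, since handling-time
differences live near $10^{-3}$ while log-rates are order 1.

## Synthetic data

`fr_simulate_trials()` generates the full experiment: the default
`fr_design()` is 11 densities (5–300), six predator and six control vials
per density, four treatments (two prey sizes × substrate absent/present),
528 vials in all. Predator vials draw eaten counts binomially around the
depletion prediction — deliberately the same observation model the
likelihood assumes, so parameter recovery is a well-posed exercise.
Control vials recover each prey with probability `control_recovery`
(default 1); values below 1 emulate counting losses and exercise the
clamping paths. The generating truths in `fr_default_truth()` are the
canonical per-treatment magnitudes (e.g. small prey without substrate:
$b = 0.173$, $q = 0.739$, $h = 0.003$).

What the generator does *not* emulate: overdispersion beyond binomial
(vial-to-vial predator heterogeneity), correlated counting errors between
predator and control vials, and any spatial refuge mechanism — substrate
acts only through treatment-specific parameters. Passing recovery and
coverage tests therefore demonstrates internal consistency of the chain,
not robustness to real-data misspecification.

`fr_simulate_foraging()` is the independent mechanistic check: an
alternating renewal process (exponential search at rate
$a_{\mathrm{eff}} \times$ prey remaining, fixed handling pause per capture).
Its mean only approximately equals the deterministic depletion solution —
the renewal process and the mean-field ODE differ at finite $N$ — so tests
hold the Monte-Carlo mean to 5%, not to equality.

## Numerical choices

* Lambert-W: vectorized Halley iteration from a log-based start, converging
  to machine precision across the double range; arguments here are provably
  non-negative. When the argument overflows (extreme $ahN_0$ with
  $hN_0 > T$), bisection on the implicit residual over $[0, N_0]$ takes
  over at tolerance $10^{-10}$.
* Optimizer: Nelder-Mead, `reltol 1e-10` (bootstrap refits `1e-7` — CI
  endpoints are order-statistics of thousands of replicates and do not
  benefit from tighter interior convergence).
* AICc requires $n > k + 1$; fits demand at least three distinct densities.
* Percentile intervals use the default quantile definition; they are
  invariant under permutation of replicates and under linear rescaling of
  parameters.

## Problem sizes used in validation

The test suite validates the statistical properties at the full design (66
predator vials per treatment): 100-dataset parameter recovery and model
selection, 200-run shape-diagnostic detection rates, 100-dataset bootstrap
coverage at 500 resamples, and 100-run power/size studies for the pooled
comparison. The acceptance script repeats the same computations at 30-50
datasets and 300 resamples to give a quick, single-command reproduction;
both scales use the same generators and seeds drive every random draw.

## Worked example

```{r example, eval = FALSE}
trials <- fr_simulate_trials(seed = 1)
prepared <- fr_prepare_trials(trials)
small <- filter(prepared, prey_size == "small", substrate == "absent")

fit2 <- fr_fit(small, model = "typeII", seed = 1)
fitf <- fr_fit(small, model = "flexible", seed = 1)
fr_compare_models(fit2, fitf)
tidy(fitf)

boot <- fr_bootstrap(fitf, n_boot = 500, seed = 1)
band <- fr_curve_band(boot, seq(5, 300, by = 5))
autoplot(band)
```

## Known limitations

* No type I (linear) model, no multi-prey or predator-interference
  extensions, and no overdispersion correction; badly overdispersed data
  will produce optimistic standard errors.
* Profile-likelihood and BCa intervals are not implemented; percentile
  intervals can undercover for strongly skewed replicate distributions.
* The scaling exponent applies to initial density; datasets generated under
  an instantaneous-density convention will be misfit.
* The search coefficient $b$ is the effective attack rate extrapolated to
  $N_0 = 1$, below the smallest design density, and is strongly
  anticorrelated with $\hat q$; at this design its relative standard error
  is several times larger than those of $h$ and $q$, and no optimizer can
  shrink that sampling floor. Treat $b$ in isolation with caution and
  compare treatments through the pooled difference test instead.
* Corrected initial densities are rounded to integers; with very few
  control replicates this loses a little information relative to a
  fractional-index quasi-likelihood.
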