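---
title: "Methods: a continuous-time life-course model of smoking and competing mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a continuous-time life-course model of smoking and competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesim)
```

## The model

`smokesim` simulates individual lifetimes in continuous time. Two
processes run along the age axis:

1. **Smoking behaviour.** Initiation is a constant hazard on
   [`start_age`, 24) calibrated so that the cumulative probability of
   ever smoking by the 24th birthday equals a target `P24`; initiation
   later in life is ignored. Cessation is a piecewise-constant hazard of
   successful quitting on the age bands [15, 28), [28, 33), [33, 48),
   [48, Inf), and is absorbing: the printed cessation rates describe
   *successful* quitters, so treating long-run relapse as negligible and
   folding short-run relapse into the net rate is the faithful net
   interpretation. Former smokers age through time-since-quit bins
   [0, 5), [5, 10), [10, 20), [20, Inf).
2. **Mortality.** Each cause has a baseline hazard on age bands and a
   multiplicative smoking-state relative risk. The all-cause hazard is
   the sum of the effective cause-specific hazards, so causes compete:
   the first event realized determines age and cause of death.

Because behaviour hazards do not depend on mortality, the smoking
history can be pre-sampled and then truncated at death. This decoupling
is what makes a deterministic oracle possible: conditional on a fixed
history the total hazard is piecewise constant with breakpoints at the
hazard-band edges and at initiation, quit, and quit + 5/10/20 years.

## Exact inversion sampling

Death is sampled by inverting the cumulative hazard: draw `E ~ Exp(1)`
and solve `Lambda(T) = E` where `Lambda` is the piecewise-linear
cumulative total hazard along the individual's segment schedule. The
crossing segment is found among the (global band edge + personal
breakpoint) knots and the death age solved in closed form; the cause is
drawn with probability proportional to the effective cause-specific
hazards of that segment. We chose inversion over thinning or
discrete-time stepping because it is exact — a property the test suite
asserts directly: re-integrating `Lambda` to each sampled death age
reproduces its `E` to below 1e-10 relative error — and because it makes
hazard updates at behaviour changes automatic rather than an
approximation-order decision.

Ties resolve deterministically: an event exactly at a breakpoint uses
the pre-breakpoint hazards, and half-open intervals make every lookup
unambiguous (a quit duration of exactly 20 years is in the [20, Inf)
bin). Any survivor at the age cap (`max_age`, default 110) dies of the
residual cause at that instant; under realistic hazards this affects a
negligible sliver of the cohort but guarantees finite lifetimes.

## Randomness

Reproducibility uses a fixed budget of four uniform draws per
individual, laid out individual-major from a single seeded
Mersenne-Twister stream: (initiation, cessation, death time, cause).
Results are therefore independent of evaluation order, and enlarging a
cohort under the same seed appends individuals without disturbing the
ones already drawn. This achieves the practical guarantees of
counter-based per-individual substreams with R's native generator.

## The deterministic oracle

`survival_curve()` evaluates `S(a) = exp(-Lambda(a))` and the
cause-specific cumulative incidence functions by summing closed-form
segment integrals — no quadrature. Life expectancy is the exact integral
of `S` over [0, `max_age`]. The oracle serves three roles: it
cross-validates the stochastic engine on a battery of fixed histories;
it computes expectation-mode period deaths (a one-year follow-up of a
frozen cross-sectional population) without Monte-Carlo noise, which is
why a null-relative-risk contrast gives *exactly* zero attributable
deaths; and it generates quit-age benefit and lifespan gain curves.

Gain curves are built from exact cell integrals of the survivor
difference on a 1-year grid scaled to a birth cohort of 10,000, so the
area under the curve equals the cohort size times the life-expectancy
difference by construction; the tests verify the identity to 1e-3 years
across scenario pairs.

For period populations given only a time-since-quit *bin*, the quit
date is placed at the bin midpoint (lower edge + 2.5 years for the
open-ended bin); with a one-year horizon and five-year bins the
resulting bin-crossing error is second order.

## Rates, units and defaults

Printed "annual rates of X%" are ingested as continuous-time hazards
X/100 per year, not annual probabilities; at the magnitudes involved
(≤ 6%/year) the difference is second order, and using hazards keeps
every piece of the model in one consistent currency. The default
smoking law is the 1980-birth-cohort calibration: cumulative initiation
0.35 (women) / 0.39 (men), cessation hazards 0.042/0.031/0.025/0.045
per year for women and 0.040/0.028/0.021/0.060 for men on the four age
bands. The initiation window starts at age 12 — the youngest cessation
band begins at 15, so smokers must exist by then; the exact start age is
configurable and the cumulative-initiation closed form makes the choice
nearly inconsequential for adult prevalence.

Scenario 3 ("always smokers") sets cumulative initiation to 1, the
degenerate limit in which everyone initiates at the start age; the
constructor accepts the closed interval [0, 1] for this reason, while
`initiation_hazard()` itself requires p < 1 because no finite hazard
attains 1.

## Calibration

Cross-sectional current-smoker prevalence among survivors differs from
the no-mortality law because smokers die faster. `survivor_prevalence()`
combines the closed-form state law with state-specific survival: the
exact state *totals* come from the analytic no-mortality solution, and
a lattice over initiation age (exact sub-interval masses) and quit age
(exact conditional masses on a 1-year step grid) supplies the survival
weighting within each state. With all relative risks equal to 1 the
survival factor cancels and the estimator reduces *exactly* to the
analytic law; in general the only approximation is the within-state
placement of lattice nodes, which is second order in the grid steps.

`calibrate()` is iterative proportional fitting in rate space: each
pass rescales cumulative initiation toward the youngest-band target and
each cessation-band hazard toward the target log-decline across the
ages it governs, with geometric damping 0.8, recomputing the
deterministic estimator between passes. The procedure was designed for
monotone, reproducible convergence rather than speed — it typically
converges in well under ten passes — and a run that stops improving
returns its best iterate with a flag rather than raising. Round-trip
tests (targets generated from known rates, started from twice the
truth) recover every parameter within 2% relative error.

## Relative-risk estimation

The estimator fits, per cause, a piecewise-exponential proportional-
hazards model: records are split at every age-band edge and smoking
breakpoint into person-periods (exposure and events conserved exactly),
aggregated by stratum (sex × 5-year age band) and smoking state, and
the Poisson-equivalent likelihood is maximized with one free baseline
per stratum profiled out analytically and five free log relative risks
(never smoking is the reference). Newton-Raphson with step-halving
stops when the gradient infinity-norm falls below 1e-8. With baselines
stratified on the same 5-year bands, this is asymptotically equivalent
to an age-stratified Cox partial-likelihood fit — a deliberate
methodological substitution that makes the likelihood, gradients and
profiling fully explicit. The tests cross-check the solver against an
independent Poisson GLM with stratum factors and verify closed-form
two-group rate ratios, exposure-scale invariance, null recovery, and
95% Wald-interval coverage on engine-generated data. A state with
exposure but no events anywhere is reported as a boundary estimate
(log RR = −Inf) with a flag.

Confounder adjustment is out of scope: the synthetic data generator
produces no confounding, so unadjusted estimates are consistent by
construction. Survey design features (weights, clustering) are likewise
not modelled.

## The synthetic world

`synthetic_spec()` defines a six-cause world: ischemic-heart-disease-,
lung-cancer-, COPD-, injury-, and other-cancer-like causes plus a
residual. Baselines are Gompertz (`level × exp(slope × age)`) on 5-year
bands — the minimal realistic shape for adult mortality, two parameters
per cause — with an essentially flat age profile for injuries. The
default levels and slopes were chosen once so that never-smoker life
expectancy lands near 81 (women) / 76 (men) years and the cause mix is
plausible for a 2004-like population; the lung-cancer and COPD relative
risks (current-smoker RR 20 and 12, decaying monotonically toward 1
with time since quitting) dominate the smoking-attributable burden, and
injuries carry RR 1 throughout as a negative control.

What the generator does *not* emulate: calendar-period trends (rates
are frozen, as in a life-table calculation), confounding, smoking
intensity, relapse, passive smoking, intergenerational effects, and
survey nonresponse. Passing tests therefore demonstrate the internal
correctness of the engine, estimators and reporting — not that the
synthetic magnitudes match any real population. The published
per-scenario life expectancies and grouped attributable-death tables
shipped in `inst/extdata/` are treated as *inputs* to the reporting
layer (its decomposition and share arithmetic is exercised against
them); the cause-level tables needed to regenerate them from scratch
are not public.

## Problem sizes

Default test and acceptance runs use cohorts of 1e5 for engine/oracle
agreement and distributional invariances, 2e4–5e4 linked records per
replicate for estimator recovery, and expectation mode (no sampling)
wherever a deterministic answer exists. These sizes give Monte-Carlo
standard errors comfortably inside every asserted tolerance while
keeping a full run at desk scale.

## Known limitations

* Cessation is absorbing; explicit relapse dynamics would need an extra
  state and rates the net-rate interpretation deliberately avoids.
* Period mode freezes the population composition over the horizon
  except for quit-duration aging; births and migration are not modelled.
* The calibration update assigns each inter-target decline to the
  cessation band containing most of it, so targets should be roughly
  band-aligned; heavily misaligned targets will still converge to a
  fixed point but identify band mixtures.
* Wald intervals are used throughout; no robust/clustered variance.
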