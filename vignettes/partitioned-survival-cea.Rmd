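---
title: "Methods: a three-state partitioned survival cost-effectiveness model for second-line therapy in advanced intrahepatic cholangiocarcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Advanced intrahepatic cholangiocarcinoma (ICC) with *FGFR2*
fusions/rearrangements can be treated in the second line with the oral FGFR
inhibitor pemigatinib (13.5 mg daily, two weeks on / one off) or with
intravenous chemotherapy — mFOLFOX (oxaliplatin + folinic acid +
fluorouracil) or 5-FU with leucovorin. `psmcea` implements the
cost-effectiveness comparison of these three strategies from the
perspective of Taiwan's National Health Insurance Administration: a
three-state partitioned survival model (PSM) with probabilistic and
deterministic sensitivity analysis, value-of-information analysis, and a
price-reduction scenario grid for the pemigatinib listing price. The
shipped configuration fixture (`default_config()`) carries the full
published parameter table of that evaluation: trial-derived survival
parameters (FIGHT-202 for pemigatinib, ABC-06 for mFOLFOX, NIFTY for
5-FU), claims-derived costs in 2022 NT$, and literature utilities.

## The model

Three mutually exclusive states — progression-free (PF), progressed disease
(PD), dead — with occupancy read directly off the survival curves rather
than from transition probabilities:

* `pf(t) = min(PFS(t), OS(t))`
* `pd(t) = OS(t) − pf(t)`
* `dead(t) = 1 − OS(t)`

The clip of PFS at OS guarantees non-negative PD occupancy when the two
fitted curves cross in the extrapolated tail; it is the package's rule, as
no standard exists. A consequence the PSM shares with all partitioned
survival analyses is that PF-state and PD-state mortality cannot be
separated; nothing in the package attempts that attribution.

Occupancy is evaluated once per cycle, by default at the cycle **midpoint**
(a trapezoid-style half-cycle correction; set
`model_settings(half_cycle_correction = FALSE)` for end-of-cycle
evaluation), and each quantity accrues as occupancy x rate x cycle length x
discount factor, with the continuous-time discount factor
`v(t) = (1 + r)^{-t}` (`r` = 0.03/year by default) evaluated at the same
time point. Tests verify that this cycle sum agrees with adaptive
quadrature of the same integrands to within 0.2%, and that halving the
cycle length moves discounted life-years by under 0.1%.

**Cycle length.** One month (12 cycles/year). The published per-cycle
medication costs divided by the printed annual rates imply roughly 29-day
cycles, and the first-cycle adverse-event decrement (below) reproduces the
published PF QALYs on a one-month window. Configurable through
`model_settings(cycles_per_year = )`; the convergence test above is the
guard.

**Horizon and threshold.** Five years; willingness to pay NT$2,928,570 per
QALY (three times the forecast 2022 GDP per capita).

## Survival inputs

Time is in months everywhere (the log-normal intercepts then reproduce the
trials' published medians, e.g. `exp(1.834) = 6.26` months for mFOLFOX
overall survival). Three families are supported, in the
accelerated-failure-time parameterizations of standard fitting software:

* Weibull, `S(t) = exp(−(t/scale)^shape)` — pemigatinib OS is
  Weibull(22.065, 1.536), median `22.065 · (ln 2)^{1/1.536} ≈ 17.4` months;
* log-normal, `S(t) = 1 − Φ((ln t − meanlog)/sdlog)`;
* generalized gamma in the Prentice (location, scale, shape `Q`)
  parameterization of **flexsurv**, with `Q = 1` and `Q = 0` recovering the
  Weibull and log-normal exactly (tested on a grid).

The published evaluation named a generalized gamma for 5-FU PFS but printed
only the two log-normal parameters (0.8, 1.067); the fixture therefore uses
the printed log-normal, and the third parameter is deliberately not
guessed. Alternative families can be supplied per arm/endpoint through
`scenario_spec(survival_overrides = )`.

**Extrapolation-only base case.** The published analysis used hybrid
curves — within-trial Kaplan-Meier splined to a parametric tail — but the
trial-level KM data are not public. The shipped base case therefore runs on
the pure parametric laws for all `t`. `build_hybrid()` implements the
hybrid construction (KM up to a switch time, then the parametric tail
rescaled by `KM(t*)/S_tail(t*)` so the curve is continuous and monotone — a
splicing rule the package had to choose, since none is standard), and it is
exercised on synthetic trials. This input difference, not the engine, is
what the reproduction checks in `tests/testthat/test-acceptance.R` resolve:
the checks that depend only on engine arithmetic and sampling pass, while
those deterministic targets that inherit the KM-versus-parametric gap in
the mFOLFOX OS and pemigatinib PFS curves sit outside their 2% bands and
are reported as computed, not adjusted.

## Costs, utilities, adverse events

PF-state accruals: the arm's annual medication rate plus its nonmedication
rate (times an optional conversion factor, a scenario lever with value
0.9). PD-state accrual: supportive care at NT$497,710/year for all arms.
Costs accrue as continuous annual rates x discounted state time, not as
per-administration events.

The one-off NT$30,000 *FGFR2* genetic-testing fee defaults to
`testing_policy = "intervention_only"`: only patients selected by testing
receive pemigatinib, and the published arm totals reconcile with the fee on
the intervention arm and not on the comparators. The policy is
configurable (`"none"`, `"all_arms"`).

Utilities: PF 0.76, PD 0.68. Two disutilities: 0.025 applied to the PF
utility of intravenously treated arms for their whole PF duration, and 0.16
for grade ≥ 3 adverse events applied to the affected proportion of each arm
(56% / 54% / 18%). By default the AE decrement is a one-off loss of one
cycle length charged undiscounted at model start — everyone is alive and on
treatment in cycle 1 — matching the convention that all adverse events
occur in the first cycle. `ae_duration_mode` extends the window to the
first six months or the whole horizon as per-cycle losses weighted by the
proportion alive (scenario analyses).

## Uncertainty analysis

**Tornado (one-way DSA).** Survival parameters move across their printed
95% confidence intervals; horizon 3–15 years; discount 0–5%; all other
parameters ±25%. Output is the INMB swing by default (`output = "icer"`
optional, since the published tornado is labelled in cost-per-QALY terms
but its metric is not stated).

**PSA.** 1000 Monte Carlo iterations by default. Distributions follow the
published table: normal for survival parameters (resampled while ≤ 0, at
most 100 attempts), uniform for the pemigatinib medication cost and the
testing fee, beta for utilities and the AE disutility, and gamma for the
remaining costs interpreted as **(mean, SD) and moment-matched** to
shape/rate — in every printed row the first gamma argument equals the
base-case mean, which identifies that convention; this interpretation is
deliberate and flagged here because a (shape, rate) reading would be
radically different. The AE proportions and the IV disutility have no
published distribution and stay fixed. Parameters are sampled
independently (no correlation structure is published), which ignores the
scale–shape correlation a joint fit would induce; each parameter draws from
its own seed-derived substream so adding a parameter never perturbs the
others' draws, and the whole PSA is bit-reproducible given the master seed.
The conversion factor, although it has a published Uniform(0.8, 1)
distribution, is held at 1 in the base-case PSA because the published
comparator cost components reconcile without it; it is sampled only inside
the conversion-factor scenario.

**CEAC and EVPI.** The acceptability curve is the fraction of draws with
positive INMB across a WTP grid (0–6M NT$ in 100k steps, always including
the threshold). EVPI is `E[max_s NMB_s] − max_s E[NMB_s]` computed
**pairwise** — intervention versus one comparator at a time — matching the
two per-comparator EVPI figures of the reference evaluation rather than a
three-way decision problem.

## Scenarios

`price_reduction_grid()` scales the pemigatinib annual medication cost (and
the bounds of its uniform PSA distribution, proportionally) by
`1 − reduction` over 0–60% in 10% steps; nothing else changes, matching the
per-tablet framing of the price discussion. `standard_scenarios()` adds
life-year effectiveness, the two AE-window variants and the 0.9 conversion
factor. Deterministic INMB is linear and strictly increasing in the
reduction (tested).

## The synthetic-trial generator

`simulate_trial()` emulates what the analysis assumes about the trials:
per-subject event times drawn by inverse CDF from the configured OS law and
a candidate progression time from the PFS law, with the recorded PFS time
the minimum of the two (progression cannot outlive death) and
administrative censoring at a fixed horizon. Default size is 100 per arm —
the order of magnitude of the real second-line ICC trials — with larger
sizes used where consistency is the question.

The joint PFS–OS structure is *not* identified by published survival
curves, so it is a modeling choice: by default the two times share one
uniform draw (comonotone coupling). Because the PFS law lies below the OS
law except far in the tail, the minimum then almost never binds, the
observed PFS marginal remains the generating law, and refitting the PFS
family by maximum likelihood stays consistent — which is what makes the
end-to-end check (refit CEA within 0.05 incremental QALYs of the true-law
CEA at n = 5000/arm) meaningful. `dependence = "independent"` is available;
it yields an observed PFS marginal `S_PFS · S_OS`.

What the generator does **not** emulate: dropout or non-administrative
censoring, covariates and eligibility, accrual over calendar time, and
patient-level cost or utility heterogeneity (the CEA consumes aggregate
rates). Passing recovery tests therefore demonstrates internal consistency
of the pipeline, not fidelity to any real trial's data-generating process.

## Numerical choices

* `fit_mle()` maximizes the right-censored log-likelihood with BFGS on
  log-transformed positive parameters (the gengamma `Q` unconstrained),
  from three starting points; non-convergence is warned, never silently
  accepted. Wald CIs come from the inverse Hessian by the delta method.
  The independent cross-check in the tests is `flexsurv::flexsurvreg()` on
  the same likelihood.
* Restricted means use adaptive quadrature (`rel.tol = 1e-10`) for smooth
  laws and a 4000-interval trapezoid for step/hybrid curves.
* `median_surv()` uses the closed-form quantile for parametric laws and
  root-finding past the switch point for hybrids.
* Degenerate inputs fail loudly: no events in a KM fit warns and returns
  the flat curve; a vanished parametric tail at the hybrid switch errors;
  out-of-domain parameters error at construction.

## Problem sizes

The shipped defaults are the analysis' own scale: 60 monthly cycles,
1000-draw PSA, 50-replicate recovery experiments at 1000 subjects/arm, and
a 5000-subject validation preset for the end-to-end refit check. All run in
seconds to a few minutes on one core.

## Known limitations

* Extrapolation-only base case where the reference analysis was hybrid
  (discussed above) — the dominant source of deviation in the reproduction
  checks.
* Independent PSA sampling overstates survival-parameter uncertainty
  relative to a correlated joint fit, which tends to *lower* the
  probability of cost-effectiveness near the threshold and shrink EVPI.
* The 5-FU PFS generalized gamma of the reference analysis is not
  reproducible from printed information; the log-normal stand-in gives that
  arm slightly less PF time.
* No budget impact, no population-level EVPI scaling, no EVPPI.
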