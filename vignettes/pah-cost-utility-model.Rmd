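---
title: "A Markov cost-utility and budget-impact model for pulmonary arterial hypertension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility and budget-impact model for pulmonary arterial hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahcea)
```

## The model

Pulmonary arterial hypertension progresses through WHO functional
classes (FC I, least severe, to FC IV), and death. The package models a
treated cohort as a discrete-time Markov chain over these five states
with a 3-month cycle, long enough to capture functional-class response
to a pulmonary selective drug and short enough that multi-step moves
within a cycle are negligible: transitions are restricted to *adjacent*
classes plus death, so each row of the transition matrix has at most
four non-zero entries.

Treatment acts multiplicatively. The baseline (standard-treatment)
switching probabilities `p(i→j)` are scaled by the drug's relative risk
of worsening (all moves to a higher class) or improvement (all moves to
a lower class), while the per-class death probabilities are taken as
common to both arms — the drugs are modelled as changing functional
status, not as changing conditional survival within a class. The stay
probability is the residual.

```{r}
p <- pah_parameters()
transition_matrix(p, "sildenafil")["fc2", ]
```

Each cycle of state membership accrues 0.25 life years, `0.25 × utility`
QALYs and the state's per-cycle cost, discounted at the cycle's start by
`(1 + r)^(-0.25 k)` with `r = 0.03` per year. A half-cycle correction
(averaging the occupancies at a cycle's start and end) is available via
`settings$half_cycle_correction` but off by default: the reward
conventions differ by under half a percent on every headline quantity
at this horizon, and the cycle-start reading is the most direct
rendering of "QALYs are life years times utility". The convention is
pinned down exactly by a brute-force oracle in the test suite that
enumerates all state paths up to eight cycles and matches the engine to
1e-9.

## Parameters

All inputs live in a single YAML configuration
(`system.file("extdata", "table1.yaml", package = "pahcea")`); every
uncertain quantity is a `{mean, se, family}` triple.

* **Transitions** (per 3 months): baseline switching probabilities
  between adjacent classes, e.g. `p(FC III→FC IV) = 0.094 (SE 0.029)`;
  beta-distributed.
* **Deaths** (per 3 months): `0.002 / 0.013 / 0.016 / 0.240` for
  FC I–IV; beta.
* **Relative risks**: sildenafil worsening `0.43`, improvement `4.23`;
  beraprost `0.10` and `0.93`; lognormal (see below).
* **Costs** (USD per 3 months): admission and outpatient-visit counts
  per class, unit costs per admission (808) and per visit (21), and
  household non-medical costs; gamma. Per-cycle drug costs (generic
  sildenafil 92, beraprost 88) carry no SE and are fixed in sampling.
  The per-visit cost of 21 (SE 2) is the value uniquely consistent with
  the aggregated per-class direct-medical totals the configuration is
  required to reproduce (e.g. `0.24·808 + 5.89·21 ≈ 317` for FC I); FC
  IV has no outpatient-visit component, making its total `0.50·808 =
  404` exact. Both are ordinary config entries and can be overridden.
* **Utilities**: `0.74 / 0.71 / 0.56 / 0.51`, beta, monotone in
  severity.
* **Settings**: 3% annual discount rate, societal perspective
  (government perspective drops the non-medical component),
  willingness-to-pay USD 3109/QALY, 20 mg-tablet prices (generic 0.34,
  originator 2.18) with 270 tablets per cycle (≈ three per day;
  `270 × 0.34 ≈ 92` reproduces the per-cycle generic cost).

`validate_parameters()` enforces completeness and domain constraints
with JSON-pointer-style error paths, and `write_parameters()` round-trips
the object losslessly.

### Why lognormal relative risks

The configuration's ratio parameters have means above 1 (a relative
risk of improvement of 4.23), which no beta distribution can represent,
so for probabilistic analysis RRs are drawn from a lognormal fitted by
method of moments — the standard choice for ratio estimates, which are
approximately normal on the log scale. This matters only for sampling:
the base case uses the means directly. The family is config-overridable
(`gamma` is also supported). The choice is consequential in one place:
a heavier right tail on the improvement RR, combined with row capping
(below), skews the sampled incremental benefit of sildenafil slightly
downward, which is visible in the FC II acceptability probability —
that starting class sits almost exactly at the threshold
(base-case ICER within 1% of the willingness to pay), so its
probability of cost-effectiveness is delicately sensitive to
distributional assumptions the mean/SE inputs do not pin down.

## The lifetime horizon

The model has no age structure and no background (non-disease)
mortality, so "lifetime" cannot be run to extinction: under sildenafil
most of the surviving cohort settles in FC I, whose quarterly death
probability is 0.002, and `choose_horizon(p, "extinction")` shows the
cohort persists for centuries, with implausible undiscounted life-year
totals. A finite horizon is therefore part of the model definition.
The default is chosen once by `calibrate_horizon()`: a grid search over
20–50 years in 5-year steps minimising the total absolute deviation of
the eight per-arm discounted and undiscounted life-year values from the
reference values stored in the configuration. The minimiser, 35 years
(140 cycles), is recorded in `settings$horizon_cycles` and used
everywhere; the calibration inputs sit beside it in the configuration
so the choice is reproducible:

```{r}
calibrate_horizon(p)
```

## Probabilistic sensitivity analysis

`run_psa()` draws every non-fixed parameter independently from its
moment-matched distribution (no covariance information exists for these
inputs). Within a draw, the baseline probabilities, death
probabilities, costs and utilities are shared between arms (common
random numbers — mirroring the relative-risk construction and reducing
Monte Carlo noise in the incrementals), while each arm's RRs are drawn
from its own distributions. Zero-SE parameters degenerate to point
masses, so a PSA with all SEs zeroed reproduces the base case draw for
draw.

A sampled row can promise more movement than probability allows
(improvement `0.125 × RR` with a large RR draw). The capping rule
rescales improvement and worsening proportionally so the row sums to 1
*with the death probability untouched* — survival is the anchored part
of the evidence — and counts the event (reported as the `capped_rows`
attribute and in run manifests); roughly one draw in six triggers it at
the default parameters. Capped or not, every sampled row is verified to
remain a valid probability vector.

`compute_ceac()` turns draws into acceptability curves on a default
willingness-to-pay grid of 0–10,000 USD in 100-USD steps (the grid is
an argument); ties in net monetary benefit are split equally, so the
two arms' probabilities sum to one at every grid point.

## One-way, price-scenario and threshold analyses

`one_way_analysis()` moves each parameter to `mean ± 1.96 SE` (clipped
to `[0, 1]` for probabilities and utilities, to zero below for
nonnegative quantities, with a warning) holding the rest at their
means, and sorts by ICER swing. The drug-price scenario comparison is
explicit: `price_scenario_analysis()` rebuilds the sildenafil per-cycle
cost from the generic or originator tablet price. `threshold_price()`
bisects a multiplier on the current sildenafil price until the
base-case ICER — taken as the maximum over the FC II and FC III starts,
so the answer holds for either population, with FC II binding — is
within 1 USD/QALY of the threshold. Because sildenafil extends life,
drug cost accrues over more discounted person-time in its own arm,
making the ICER strictly increasing in price and bisection safe; the
search brackets before it bisects and errors if the bracket fails.

## Budget impact

`project_budget()` is an open-cohort projection from a government
perspective (direct medical + drug cost, undiscounted by default, a
`discount_rate` argument is available): the prevalent pool
(`8000 × 0.5` per starting class) enters at the start of year 1
together with the first incident cohort, and a further incident cohort
(`605 × 0.5`) enters at the start of each later year; everyone is
traced quarterly through the arm's transition matrix, so mortality
attrites the pool and survivors redistribute over classes. Entry
timing is the one structural choice the inputs do not determine; the
start-of-year rule is the bundled default and is exposed through the
function's arguments rather than hidden. Note that a closed FC III
cohort becomes *more* expensive per year as survivors improve into
FC II, whose per-cycle cost is higher — the projection is not monotone
in time even without incidence, and the tests assert exactly that.

## Synthetic patient cohort

`simulate_patients()` emulates the interview/billing microdata behind
the cost and utility inputs: 48 patients split 18/19/10/1 over FC I–IV
by default, each with 3-month admission and visit counts, unit costs,
non-medical cost and utility. Counts are Poisson at the class mean —
an integer-valued, nonnegative, single-parameter law matching the mean,
which is all the configuration specifies for a count; monetary amounts
and utilities come from the fitted gamma/beta laws.
`estimate_moments()` recovers means and standard errors
(`SD/sqrt(n)`), pooling the unit costs across classes, and reports a
missing SE for a single-patient class rather than failing — the FC IV
class of one is deliberately reproducible. `update_parameters()` feeds
estimates back into a parameter set, closing the loop from microdata to
model input; with large synthetic samples the re-estimated base case
agrees with the configured one to within a few percent.

What the generator does *not* emulate: EQ-5D dimension-level responses
(no tariff is part of the model — utilities are drawn at class level),
billing-record structure, and any correlation between a patient's
costs and utility. Passing the recovery tests therefore shows the
estimation pipeline is consistent, not that real interview data would
be this clean.

## Numerical and testing choices

* Row-stochasticity is enforced to 1e-12 at construction and 1e-10
  along every trace; a post-capping stay probability within 1e-9 below
  zero (floating-point residue) is clamped to zero.
* Degenerate inputs are contracts, not errors: death-state cost is
  zero; an empty class in the synthetic cohort is allowed; identical
  arms report an undefined ICER with an explicit "indifferent" status
  rather than dividing by zero.
* The test suite runs the full 140-cycle model everywhere it is cheap,
  and scales down only where cost is superlinear: the path-enumeration
  oracle uses horizons of 4–8 cycles (4^8 paths), parameter-recovery
  loops use 100 seeds at 200 patients per class, and the in-suite PSA
  checks use 1000 draws, matching the Monte Carlo design size.
* All randomness flows through ordinary R RNG seeded at the caller:
  the same seed gives bit-identical PSA draws, curves and cohorts.

## Known limitations

* No background mortality, age structure, or treatment switching; the
  calibrated horizon is the explicit surrogate for "lifetime".
* Parameters are sampled independently; any real covariance between,
  say, class costs is not represented.
* The FC II acceptability probability is sensitive to the
  ratio-parameter family choice discussed above; the FC III
  probability and all deterministic quantities are robust to it.
* The budget projection has no uptake dynamics, market-share mixing or
  price erosion: each arm is costed as if it treated the whole
  population.
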