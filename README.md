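# pahcea

Cost-utility and budget-impact modelling of pulmonary selective drug
therapy — sildenafil versus beraprost — for pulmonary arterial
hypertension (PAH), built for health-economics analysts who need a
transparent, configuration-driven, fully tested implementation of a
published-style Markov evaluation.

PAH is a progressive disease graded by WHO functional class (FC I–IV).
The package models a cohort over five states (FC I, FC II, FC III, FC IV,
death) in 3-month cycles. Under standard treatment, patients switch
between adjacent classes with baseline probabilities `p(i→j)` and die
with class-specific probabilities `d(i)`. A drug modifies switching
multiplicatively through relative risks:

```
p_drug(worsen) = p(worsen) · RR_worsening
p_drug(improve) = p(improve) · RR_improvement
p_drug(death)  = d(i)                      (common to both arms)
p_drug(stay)   = 1 − the rest
```

Each cycle, living states accrue 0.25 life years, utility-weighted QALYs
(`QALY = LY × utility`), and costs (direct medical + household
non-medical under the societal perspective + drug), discounted at 3% a
year. The comparison is summarised by the incremental
cost-effectiveness ratio and net monetary benefit,

```
ICER = (C_sild − C_bera) / (Q_sild − Q_bera)        NMB = λ·Q − C
```

judged against a willingness-to-pay threshold λ = USD 3109 per QALY (one
times GDP per capita). Around this core the package provides:

- **`pah_parameters()`** — every model input (mean, SE, distribution
  family) in one YAML file; a transcription of the published parameter
  table is bundled as the default.
- **`run_base_case()`** — deterministic lifetime analysis at parameter
  means, with `tidy()`/`glance()` accessors.
- **`run_psa()` / `compute_ceac()`** — 1000-draw probabilistic
  sensitivity analysis with method-of-moments beta/gamma/lognormal
  sampling and cost-effectiveness acceptability curves
  (`autoplot()`/`plot_ceac()`).
- **`one_way_analysis()` / `price_scenario_analysis()` /
  `threshold_price()`** — tornado analysis, generic-vs-originator price
  comparison, and the bisection search for the price cut that makes the
  originator product cost-effective.
- **`budget_impact()`** — five-year open-cohort payer projection from
  prevalence 8000 and annual incidence 605, split 50/50 between FC II
  and FC III.
- **`simulate_patients()` / `estimate_moments()`** — synthetic
  48-patient interview/billing microdata and re-estimation of the cost
  and utility inputs from it.

## Worked example

```r
library(pahcea)
p <- pah_parameters()              # bundled defaults
run_base_case(p, start_fc = 2)
#> <pah_cea> sildenafil vs beraprost, FC II start
#> # A tibble: 2 × 9
#>   drug   start_fc perspective life_years life_years_disc qalys qalys_disc   cost
#> 1 berap…        2 societal          26.1            17.0  19.2       12.5 56957.
#> 2 silde…        2 societal          27.4            17.8  20.1       13.1 59999.
#> incremental cost     1924.73 USD
#> incremental QALYs     0.6254
#> ICER                 3077.74 USD/QALY (trade-off)
#> NMB difference at WTP 3109: 19.55 USD -> cost-effective
```

Over a lifetime (calibrated 35-year horizon), sildenafil from FC II
yields 27.4 vs 26.1 undiscounted life years and costs USD 1925 more per
patient (discounted, societal perspective) for 0.63 extra discounted
QALYs — USD 3078 per QALY gained, just under the threshold. From FC III
the ICER is USD 2836 (`glance(run_base_case(p, 3))`). How far the
originator tablet price must fall to be equally good value:

```r
threshold_price(set_price_scenario(p, "originator"))
#> # A tibble: 1 × 4
#>   multiplier percent_reduction  icer   wtp
#> 1      0.157              84.3 3109.  3109
```

an 84% price cut, at which point the originator price matches the
generic one. The five-year payer budget:

```r
budget_impact(p)$incremental
#> # A tibble: 3 × 4
#>   start_fc beraprost sildenafil incremental
#> 1 2        38643593.  39046886.     403293.
#> 2 3        32445896.  36101358.    3655462.
#> 3 combined 71089489.  75148244.    4058755.
```

adopting sildenafil costs the payer an extra USD 0.40M (FC II
population) and USD 3.66M (FC III), about USD 4.1M combined.

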