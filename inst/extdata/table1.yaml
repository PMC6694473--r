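# Default model configuration: all inputs of the PAH cost-utility model.
# Every uncertain entry is {mean, se, family}; family "fixed" means the
# value is not sampled in probabilistic analyses (se treated as 0).
# Monetary values in USD; cycle length is 3 months (0.25 years).

settings:
  annual_discount_rate: 0.03
  cycle_length_years: 0.25
  horizon_cycles: 140            # 35 years; see horizon_calibration
  wtp_per_qaly: 3109             # one times GDP per capita, USD
  perspective: societal
  half_cycle_correction: false
  currency: USD
  idr_per_usd: 13830             # display metadata only
  tablets_per_cycle: 270         # 20 mg sildenafil tablets per 3 months (~3/day)
  prices:
    sildenafil_generic_per_tablet: 0.34
    sildenafil_originator_per_tablet: 2.18
    beraprost_per_20mcg: 0.33
  # Lifetime horizon chosen once by grid search over whole-year candidates,
  # minimizing total absolute deviation from the reference discounted and
  # undiscounted life-year values below (see calibrate_horizon()).
  horizon_calibration:
    grid_years: [20, 25, 30, 35, 40, 45, 50]
    chosen_years: 35
    reference_life_years:
      - {drug: beraprost,  start_fc: 2, undiscounted: 26.75, discounted: 16.23}
      - {drug: sildenafil, start_fc: 2, undiscounted: 27.91, discounted: 16.94}
      - {drug: beraprost,  start_fc: 3, undiscounted: 23.03, discounted: 14.10}
      - {drug: sildenafil, start_fc: 3, undiscounted: 25.99, discounted: 15.80}

epidemiology:
  prevalence: 8000
  annual_incidence: 605
  fc2_fraction: 0.5
  fc3_fraction: 0.5

# Per-cycle probability of switching functional class under standard treatment
transitions:
  fc1_to_fc2: {mean: 0.127, se: 0.044, family: beta}
  fc2_to_fc1: {mean: 0.125, se: 0.033, family: beta}
  fc2_to_fc3: {mean: 0.127, se: 0.044, family: beta}
  fc3_to_fc2: {mean: 0.125, se: 0.033, family: beta}
  fc3_to_fc4: {mean: 0.094, se: 0.029, family: beta}
  fc4_to_fc3: {mean: 0.025, se: 0.023, family: beta}

# Per-cycle probability of death by functional class (both arms)
deaths:
  fc1: {mean: 0.002, se: 0.009, family: beta}
  fc2: {mean: 0.013, se: 0.009, family: beta}
  fc3: {mean: 0.016, se: 0.011, family: beta}
  fc4: {mean: 0.240, se: 0.065, family: beta}

# Relative risk of switching FC versus standard treatment.
# Ratio parameters are sampled lognormal by method of moments.
effects:
  sildenafil:
    rr_worsening:   {mean: 0.43, se: 0.380, family: lognormal}
    rr_improvement: {mean: 4.23, se: 2.043, family: lognormal}
  beraprost:
    rr_worsening:   {mean: 0.10, se: 0.199, family: lognormal}
    rr_improvement: {mean: 0.93, se: 0.612, family: lognormal}

costs:
  admissions_per_cycle:
    fc1: {mean: 0.24, se: 0.03, family: gamma}
    fc2: {mean: 0.33, se: 0.13, family: gamma}
    fc3: {mean: 0.20, se: 0.07, family: gamma}
    fc4: {mean: 0.50, se: 0.50, family: gamma}
  visits_per_cycle:
    fc1: {mean: 5.89, se: 0.48, family: gamma}
    fc2: {mean: 4.89, se: 0.47, family: gamma}
    fc3: {mean: 3.00, se: 0.47, family: gamma}
    fc4: {mean: 0.00, se: 0.00, family: fixed}   # no outpatient visits recorded in FC IV
  cost_per_admission: {mean: 808, se: 143, family: gamma}
  cost_per_visit:     {mean: 21,  se: 2,   family: gamma}
  nonmedical_per_cycle:
    fc1: {mean: 136, se: 27,  family: gamma}
    fc2: {mean: 110, se: 24,  family: gamma}
    fc3: {mean: 158, se: 64,  family: gamma}
    fc4: {mean: 364, se: 364, family: gamma}
  drug_per_cycle:
    sildenafil: {mean: 92, se: 0, family: fixed}  # generic price
    beraprost:  {mean: 88, se: 0, family: fixed}

utilities:
  fc1: {mean: 0.74, se: 0.04, family: beta}
  fc2: {mean: 0.71, se: 0.04, family: beta}
  fc3: {mean: 0.56, se: 0.03, family: beta}
  fc4: {mean: 0.51, se: 0.04, family: beta}
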