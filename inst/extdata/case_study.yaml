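# Case study: individually tailored vs two-year elastic compression stocking
# (ECS) therapy for the prevention of post-thrombotic syndrome (PTS) after
# deep vein thrombosis.
#
# Entries marked "appendix_default: true" are placeholder values for
# quantities that the published evidence base does not report in full detail
# (resource use, unit prices, utility norms, mortality, severity split); they
# are documented defaults, all overridable, not reconstructions.

model:
  threshold: 20000          # EUR per QALY
  discount_cost: 0.04       # annual discount rate, costs
  discount_effect: 0.015    # annual discount rate, (quality-adjusted) life years
  start_age: 60             # cohort age at DVT (placeholder)
  horizon_age: 100          # lifetime implemented as run-until-age cap
  severe_fraction: 0.2      # share of new PTS that is severe (placeholder)
  stop_proportion: 0.5      # tailored arm: share stopping ECS at 6 months
  utility_norm_at_start: 0.85   # age norm utility at start_age (placeholder)
  utility_norm_slope: 0.004     # utility decline per year of age (placeholder)
  mortality:                # synthetic Gompertz life table calibrated to an
    gompertz_a: 3.785631e-05  # 80-year life expectancy at birth
    gompertz_b: 0.09

population:
  annual_incidence: 25000   # patients developing PTS risk per year (NL)
  tech_lifetime: 10         # years the adoption decision stays relevant
  discount_rate: 0.04       # discounting of future incident cohorts

trial:
  fixed_cost: 10000         # EUR
  cost_per_patient: 5000    # EUR per included patient
  sample_size_grid: [25, 100, 400, 500, 700, 1000, 1500, 5000]

frequentist:
  p_standard: 0.233         # absolute risk reduction of two-year ECS at 2 years
  p_new: 0.233              # hypothesized equal for tailored therapy
  margin: 0.075             # non-inferiority margin (~70% effect preserved)
  alpha: 0.05               # one-sided
  power: 0.80

voi:
  psa_draws: 10000
  outer: 200                # simulated trial results per sample size
  inner: 1000               # posterior PSA draws per simulated trial

parameters:
  incidence:                # cumulative PTS incidence, two-year ECS arm
    c6:  {mean: 0.211, se: 0.0429}
    c12: {mean: 0.222, se: 0.0431}
    c24: {mean: 0.245, se: 0.0454}
  rr:                       # relative risk of PTS after month 6, tailored arm;
    sigma_log: 0.612        # lognormal, median 1, censored below at 1
  disutility_mild:   {family: beta-by-moments,  mean: 0.117, se: 0.050}
  disutility_severe: {family: beta-by-moments,  mean: 0.218, se: 0.040}
  disutility_ecs:    {family: beta-by-moments,  mean: 0.02,  se: 0.01,  appendix_default: true}
  cost_pts_mild:     {family: gamma-by-moments, mean: 3000,  se: 750,   appendix_default: true}
  cost_pts_severe:   {family: gamma-by-moments, mean: 6000,  se: 1500,  appendix_default: true}
  cost_stocking:     {family: fixed,            mean: 100,   se: 0,     appendix_default: true}
  homecare_fraction: {family: beta-by-moments,  mean: 0.075, se: 0.02,  appendix_default: true}
  cost_homecare:     {family: gamma-by-moments, mean: 10000, se: 2500,  appendix_default: true}
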