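# Second-line pemigatinib vs mFOLFOX vs 5-FU for advanced intrahepatic
# cholangiocarcinoma with FGFR2 fusions, payer perspective of Taiwan's NHIA.
# All monetary values in 2022 NT$; survival time scale is months.
settings:
  horizon_years: 5
  cycles_per_year: 12
  annual_discount_rate: 0.03
  wtp_per_qaly: 2928570            # 3 x forecast 2022 GDP per capita
  half_cycle_correction: true
costs:
  supportive_care_per_year: 497710
  genetic_testing_fee: 30000
  testing_policy: intervention_only
  nonmedication_conversion_factor: 1.0
utilities:
  u_pf: 0.76
  u_pd: 0.68
  disutility_ae: 0.16
  disutility_iv: 0.025
  ae_duration_mode: first_cycle
arms:
  pemigatinib:
    label: Pemigatinib
    is_intervention: true
    iv_administered: false          # oral, 13.5 mg/day, 2 weeks on / 1 off
    ae_grade3_proportion: 0.56
    medication_cost_per_year: 4336200   # NT$17,820/day list price
    nonmedication_cost_per_year: 291576
    os:  {family: weibull,   params: [22.065, 1.536]}
    pfs: {family: lognormal, params: [1.962, 0.971]}
  mfolfox:
    label: mFOLFOX
    iv_administered: true
    ae_grade3_proportion: 0.54
    medication_cost_per_year: 412087
    nonmedication_cost_per_year: 856986
    os:  {family: lognormal, params: [1.834, 0.873]}
    pfs: {family: lognormal, params: [1.430, 0.754]}
  fu:
    label: 5-FU
    iv_administered: true
    ae_grade3_proportion: 0.18
    medication_cost_per_year: 177759
    nonmedication_cost_per_year: 856986
    os:  {family: lognormal, params: [1.764, 0.816]}
    pfs: {family: lognormal, params: [0.8, 1.067]}
# Deterministic bounds: survival parameters at their 95% CIs; horizon 3-15 y;
# discount 0-5%; everything else +/- 25%. PSA: normal survival parameters
# (truncated positive), uniform pemigatinib medication cost and testing fee,
# moment-matched gamma (mean, SD) costs, beta utilities/disutility; the
# adverse-event proportions and IV disutility have no published distribution
# and stay fixed in the PSA.
parameters:
  - {name: os_pem_scale,       base: 22.065, low: 17.486, high: 27.843,
     dist: normal, args: [22.065, 2.619]}
  - {name: os_pem_shape,       base: 1.536,  low: 1.184,  high: 1.993,
     dist: normal, args: [1.536, 0.204]}
  - {name: pfs_pem_meanlog,    base: 1.962,  low: 1.760,  high: 2.164,
     dist: normal, args: [1.962, 0.103]}
  - {name: pfs_pem_sdlog,      base: 0.971,  low: 0.820,  high: 1.150,
     dist: normal, args: [0.971, 0.084]}
  - {name: os_mfolfox_meanlog, base: 1.834,  low: 1.642,  high: 2.023,
     dist: normal, args: [1.834, 0.098]}
  - {name: os_mfolfox_sdlog,   base: 0.873,  low: 0.742,  high: 1.027,
     dist: normal, args: [0.873, 0.072]}
  - {name: pfs_mfolfox_meanlog, base: 1.430, low: 1.265,  high: 1.595,
     dist: normal, args: [1.430, 0.084]}
  - {name: pfs_mfolfox_sdlog,  base: 0.754,  low: 0.643,  high: 0.885,
     dist: normal, args: [0.754, 0.062]}
  - {name: os_fu_meanlog,      base: 1.764,  low: 1.586,  high: 1.943,
     dist: normal, args: [1.764, 0.091]}
  - {name: os_fu_sdlog,        base: 0.816,  low: 0.691,  high: 0.965,
     dist: normal, args: [0.816, 0.070]}
  - {name: pfs_fu_meanlog,     base: 0.8,    low: 0.570,  high: 1.031,
     dist: normal, args: [0.8, 0.118]}
  - {name: pfs_fu_sdlog,       base: 1.067,  low: 0.910,  high: 1.251,
     dist: normal, args: [1.067, 0.087]}
  - {name: genetic_testing_fee, base: 30000, low: 22500,  high: 37500,
     dist: uniform, args: [22500, 37500]}
  - {name: cost_med_pem,       base: 4336200, low: 3252150, high: 5420250,
     dist: uniform, args: [3252150, 5420250]}
  - {name: cost_med_mfolfox,   base: 412087, low: 309065, high: 515108,
     dist: gamma, args: [412087, 617747]}
  - {name: cost_med_fu,        base: 177759, low: 133320, high: 222199,
     dist: gamma, args: [177759, 282466]}
  - {name: cost_nonmed_pem,    base: 291576, low: 218682, high: 364470,
     dist: gamma, args: [291576, 691057]}
  - {name: cost_nonmed_chemo,  base: 856986, low: 642740, high: 1071233,
     dist: gamma, args: [856986, 1067455]}
  - {name: cost_supportive,    base: 497710, low: 373283, high: 622138,
     dist: gamma, args: [497710, 576562]}
  - {name: u_pf,               base: 0.76,   low: 0.57,   high: 0.95,
     dist: beta, args: [4.7, 1.5]}
  - {name: u_pd,               base: 0.68,   low: 0.51,   high: 0.85,
     dist: beta, args: [29, 13.6]}
  - {name: disutility_iv,      base: 0.025,  low: 0.0188, high: 0.0313,
     dist: fixed}
  - {name: disutility_ae,      base: 0.16,   low: 0.12,   high: 0.20,
     dist: beta, args: [36, 193]}
  - {name: ae_prop_pem,        base: 0.56,   low: 0.42,   high: 0.70,
     dist: fixed}
  - {name: ae_prop_mfolfox,    base: 0.54,   low: 0.405,  high: 0.675,
     dist: fixed}
  - {name: ae_prop_fu,         base: 0.18,   low: 0.135,  high: 0.225,
     dist: fixed}
  - {name: discount_rate,      base: 0.03,   low: 0.0,    high: 0.05,
     dist: fixed}
  - {name: horizon_years,      base: 5,      low: 3,      high: 15,
     dist: fixed}
seed: 1
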