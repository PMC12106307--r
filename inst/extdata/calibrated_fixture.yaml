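states:
- state_without_complications
- state_with_multiple_complications
- necessary_tracheostomy
- necessary_enteral_feeding
- epilepsy
- interstitial_lung_disease
- major_bleeding
- death
adjacency:
  state_without_complications:
  - state_without_complications
  - state_with_multiple_complications
  - necessary_tracheostomy
  - necessary_enteral_feeding
  - epilepsy
  - interstitial_lung_disease
  - major_bleeding
  - death
  state_with_multiple_complications:
  - state_with_multiple_complications
  - death
  necessary_tracheostomy:
  - necessary_tracheostomy
  - death
  necessary_enteral_feeding:
  - necessary_enteral_feeding
  - death
  epilepsy:
  - epilepsy
  - death
  interstitial_lung_disease:
  - interstitial_lung_disease
  - death
  major_bleeding:
  - major_bleeding
  - death
  death:
  - death
transitions:
  mono:
  - from: state_without_complications
    to: state_with_multiple_complications
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: necessary_tracheostomy
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: necessary_enteral_feeding
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: epilepsy
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: interstitial_lung_disease
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: major_bleeding
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: death
    prob: 0.0286510788909807370684
  - from: state_with_multiple_complications
    to: death
    prob: 0.0859532366729422181439
  - from: necessary_tracheostomy
    to: death
    prob: 0.0859532366729422181439
  - from: necessary_enteral_feeding
    to: death
    prob: 0.0859532366729422181439
  - from: epilepsy
    to: death
    prob: 0.0859532366729422181439
  - from: interstitial_lung_disease
    to: death
    prob: 0.0859532366729422181439
  - from: major_bleeding
    to: death
    prob: 0.0859532366729422181439
  combo:
  - from: state_without_complications
    to: state_with_multiple_complications
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: necessary_tracheostomy
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: necessary_enteral_feeding
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: epilepsy
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: interstitial_lung_disease
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: major_bleeding
    prob: 0.0033333333333333335473
  - from: state_without_complications
    to: death
    prob: 0.0161245080886922437235
  - from: state_with_multiple_complications
    to: death
    prob: 0.0483735242660767311706
  - from: necessary_tracheostomy
    to: death
    prob: 0.0483735242660767311706
  - from: necessary_enteral_feeding
    to: death
    prob: 0.0483735242660767311706
  - from: epilepsy
    to: death
    prob: 0.0483735242660767311706
  - from: interstitial_lung_disease
    to: death
    prob: 0.0483735242660767311706
  - from: major_bleeding
    to: death
    prob: 0.0483735242660767311706
utilities:
  state_without_complications: 0.8599999999999999866773
  state_with_multiple_complications: 0.4400000000000000022204
  necessary_tracheostomy: 0.6800000000000000488498
  necessary_enteral_feeding: 0.5
  epilepsy: 0.5500000000000000444089
  interstitial_lung_disease: 0.5500000000000000444089
  major_bleeding: 0.5200000000000000177636
  death: 0.0
drugs:
  imiglucerase:
    pack_size: 400.0
    pack_price: 21870.0
    dose_per_admin: 2.5
    admins_per_week: 3.0
  ambroxol:
    pack_size: 600.0
    pack_price: 5.25
    daily_dose_per_kg: 25.0
weight_kg: 20.0
cost_multiplier:
  imiglucerase_mono: 0.6709331113259882073407
  imiglucerase_plus_ambroxol: 0.5830213348356709790465
economics:
  discount_rate: 0.0500000000000000027756
  horizon_years: 6.0
  cycle_length_months: 1.0
  gdp_per_capita: 89358.0
  wtp_multipliers:
  - 1.0
  - 2.0
  - 3.0
  half_cycle: yes
psa:
  n_draws: 1000.0
  se_fraction: 0.1000000000000000055511
  sample_transitions: no
  wtp_points: 21.0
owsa:
  fraction: 0.1000000000000000055511
  parameters:
  - imiglucerase_price
  - ambroxol_price
  - utility.state_without_complications
  - utility.state_with_multiple_complications
  - utility.necessary_tracheostomy
  - utility.necessary_enteral_feeding
  - utility.epilepsy
  - utility.interstitial_lung_disease
  - utility.major_bleeding
  - discount_rate

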