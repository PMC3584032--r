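arms:
  lpvr:
    name: LPV/r
    tc_hdl_effect: -0.17
    primary_ae: diarrhoea
    ae_risk: 1.76
    vl_reduction: 0.0
  atvr1:
    name: ATV+r 1
    tc_hdl_effect: -0.4
    primary_ae: hyperbilirubinemia
    ae_risk: 1.47
    vl_reduction: 0.0
  atvr2:
    name: ATV+r 2
    tc_hdl_effect: -0.4
    primary_ae: hyperbilirubinemia
    ae_risk: 1.47
    vl_reduction: 0.19
risks:
  chd_base:
    none: 0.17
    dm: 0.82
    chd: 3.75
    dm_chd: 4.94
  chd_fatal: 35.4
  chd_rr_per_unit_tc_hdl: 0.14
  oi: 1.76
  aids:
  - 0.09
  - 1.62
  - 1.04
  - 5.85
  - 2.12
  - 22.76
  - 69.34
  - 94.35
  aids_case_fatality: 0.0
  ckd_ramp:
    lpvr:
      start: 0.12
      end: 2.9
    atvr:
      start: 0.12
      end: 23.3
    n_cycles: 40.0
costs:
  hs_annual:
    lpvr:
    - 11423.24
    - 11563.34
    - 11621.42
    - 11575.639999999999
    - 11837.66
    - 11753.780000000001
    - 11895.84
    - 11409.780000000001
    atvr:
    - 11439.4
    - 11579.48
    - 11637.559999999999
    - 11591.780000000001
    - 11853.799999999999
    - 11769.940000000001
    - 11912.0
    - 11425.940000000001
  event:
    aids: 4684.0
    chd: 1354.07
    oi: 2110.69
    hyperbilirubinemia: 27.61
    diarrhoea: 50.82
    ckd: 1185.36
utilities:
  hs:
  - 0.944
  - 0.935
  - 0.929
  - 0.932
  - 0.863
  - 0.849
  - 0.781
  - 0.781
  hs_chd:
  - 0.6006
  - 0.6
  - 0.5996
  - 0.5998
  - 0.6002
  - 0.6007
  - 0.6005
  - 0.6005
  event:
    aids:
    - 0.56
    - 0.56
    - 0.56
    - 0.56
    - 0.56
    - 0.56
    - 0.56
    - 0.56
    oi:
    - 0.62
    - 0.62
    - 0.62
    - 0.62
    - 0.62
    - 0.62
    - 0.62
    - 0.62
    hyperbilirubinemia:
    - 0.8835
    - 0.8824
    - 0.8816
    - 0.882
    - 0.8725
    - 0.8704
    - 0.8592
    - 0.8592
    diarrhoea:
    - 0.8273
    - 0.8257
    - 0.8245
    - 0.8251
    - 0.8111
    - 0.808
    - 0.7913
    - 0.7913
    ckd:
    - 0.8835
    - 0.8824
    - 0.8816
    - 0.882
    - 0.8725
    - 0.8704
    - 0.8592
    - 0.8592
  second_line: 0.781
  combine: minimum
economics:
  annual_discount_rate: 0.03
  wtp_threshold: 25000.0
  cycle_length: 0.5
  cohort_size: 500000.0
transitions:
  diagonals:
    lpvr:
    - 0.70721
    - 0.86111
    - 0.38737
    - 0.45253
    - 0.05202
    - 0.13132
    - 0.01623
    - 0.02844
    atvr1:
    - 0.77487
    - 0.71106
    - 0.29664
    - 0.36481
    - 0.08941
    - 0.09041
    - 0.00485
    - 0.02175
    atvr2:
    - 0.7232
    - 0.8698
    - 0.40847
    - 0.47386
    - 0.05719
    - 0.14281
    - 0.01791
    - 0.03135
    second:
    - 0.49504
    - 0.60277
    - 0.27118
    - 0.31675
    - 0.0364
    - 0.09191
    - 0.01134
    - 0.01988
  completion_scheme: rank_proportional
demographics:
  age_mean: 39.2
  age_sd: 9.5
  min_age: 18.0
  male_fraction: 75.9
  prior_dm: 3.8
  prior_chd: 1.2
  start_state_probs:
  - 0.0
  - 0.45
  - 0.0
  - 0.35
  - 0.0
  - 0.15
  - 0.0
  - 0.05
life_table:
  makeham:
    male:
      a: 0.0002
      b: 2.7e-05
      g: 0.093
    female:
      a: 0.0001
      b: 1.3e-05
      g: 0.099
  mrr: 3.0
  max_age: 110.0
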