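probabilities:
  intervention:
    noaf:
      events: 2
      'n': 13
    lco_given_noaf:
      events: 0
      'n': 2
    lco_given_no_noaf:
      events: 2
      'n': 11
    rf_given_lco:
      events: 0
      'n': 2
    rf_given_no_lco:
      events: 1
      'n': 11
    mv_given_lco:
      events: 0
      'n': 2
    mv_given_no_lco:
      events: 1
      'n': 11
    shock_given_lco:
      events: 0
      'n': 2
    death_given_shock:
      events: 0
      'n': 13
  control:
    noaf:
      events: 9
      'n': 41
    lco_given_noaf:
      events: 7
      'n': 9
    lco_given_no_noaf:
      events: 18
      'n': 32
    rf_given_lco:
      events: 9
      'n': 25
    rf_given_no_lco:
      events: 1
      'n': 16
    mv_given_lco:
      events: 8
      'n': 25
    mv_given_no_lco:
      events: 1
      'n': 16
    shock_given_lco:
      events: 10
      'n': 25
    death_given_shock:
      events: 5
      'n': 10
los:
  icu_base:
    intervention: 1.346153846153846
    control: 1.870731707317074
  ward_base:
    intervention: 6.306153846153846
    control: 6.046341463414635
  icu_increment:
    noaf: 1.0
    lco: 4.0
    rf: 3.0
    mv: 2.0
  ward_increment:
    noaf: 0.5
    lco: 0.0
    rf: 1.0
    mv: 0.0
profiles:
  base:
    surgery: 1.0
    lab_profile: 1.0
    ecg: 2.0
    echo: 2.0
  per_icu_day:
    icu_day: 1.0
    lab_profile: 1.75
    ecg: 1.0
    acetaminophen_iv: 3.0
    furosemide_iv: 2.0
    dalteparin: 1.0
  per_ward_day:
    ward_day: 1.0
    atorvastatin: 1.0
    bisoprolol: 1.0
    asa: 1.0
    dalteparin: 1.0
  upfront_intervention:
    levosimendan: 1.0
    ccu_day: 1.0
    ward_day: 1.0
    lab_profile: 3.0
    ecg: 2.0
    echo: 2.0
  noaf:
    amiodarone_iv: 6.0
    amiodarone_tab: 30.0
  lco:
    echo: 4.0
    dobutamine: 12.0
    norepinephrine: 8.0
  rf:
    hemofilter_kit: 1.0
    effluent_bag: 10.0
  mv:
    mech_vent_icu: 2.0
    oral_paste: 2.0
    decontam_solution: 1.0
psa:
  n_draws: 10000.0
  ess: 75.0
  gamma_bound: 0.1
  uniform_bound: 0.1
  shared_cost_draws: yes
  ci_level: 0.95
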