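libraries:
  Pfizer: 81
  FDA: 875
wt:
  tm_c: 65.0
  dh_vh: 55.0
  f_base: 1000.0
  f_amp: 9000.0
  base_slope_f: 0.0
  base_slope_u: 0.0
  decay_rate: 0.0
  noise_sd: 0.0
mutant:
  tm_c: 47.0
  dh_vh: 35.0
  f_base: 1000.0
  f_amp: 9000.0
  base_slope_f: 0.0
  base_slope_u: 0.0
  decay_rate: 0.0
  noise_sd: 0.0
hits:
  Pfizer:
  - 8
  - 12
  - 23
  - 37
  - 45
  - 61
  - 77
  FDA:
  - 9
  - 40
  - 99
  - 150
  - 222
  - 310
  - 401
  - 487
  - 550
  - 701
  - 860
interference:
- FDA-130
- FDA-600
- FDA-750
candidates:
  Pfizer-008:
    name: atorvastatin
    ans_corrector: yes
    tm_dose:
      ec50: 0.32
      dtm_max: 18.0
    itc:
      ec50: 0.4
      q_max: 200.0
      syringe_conc_mM: 5.0
    viability:
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    efflux_restores: yes
    optimal_conc_mM: 0.2
  FDA-009:
    name: bexarotene
    ans_corrector: yes
    tm_dose:
      ec50: 0.059
      dtm_max: 18.0
    itc:
      ec50: 0.098
      q_max: 150.0
      syringe_conc_mM: 2.0
    viability:
    - 1.0
    - 1.0
    - 1.0
    - 0.75
    - 0.25
    efflux_restores: yes
    optimal_conc_mM: 0.05
  FDA-040:
    name: adapalene
    ans_corrector: yes
    tm_dose:
      ec50: 0.05
      dtm_max: 15.0
    viability:
    - 0.5
    - 0.4
    - 0.3
    - 0.2
    - 0.1
    efflux_restores: no
    optimal_conc_mM: 0.05
  FDA-099:
    name: lovastatin
    ans_corrector: yes
    tm_dose:
      ec50: 0.1
      dtm_max: 0.5
    viability:
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    efflux_restores: no
    optimal_conc_mM: 0.1
assays:
  grid:
    min: 20.0
    max: 80.0
    step: 0.5
  screen_conc_mM: 0.1
  ans:
    grid_nm:
    - 425.0
    - 426.0
    - 427.0
    - 428.0
    - 429.0
    - 430.0
    - 431.0
    - 432.0
    - 433.0
    - 434.0
    - 435.0
    - 436.0
    - 437.0
    - 438.0
    - 439.0
    - 440.0
    - 441.0
    - 442.0
    - 443.0
    - 444.0
    - 445.0
    - 446.0
    - 447.0
    - 448.0
    - 449.0
    - 450.0
    - 451.0
    - 452.0
    - 453.0
    - 454.0
    - 455.0
    - 456.0
    - 457.0
    - 458.0
    - 459.0
    - 460.0
    - 461.0
    - 462.0
    - 463.0
    - 464.0
    - 465.0
    - 466.0
    - 467.0
    - 468.0
    - 469.0
    - 470.0
    - 471.0
    - 472.0
    - 473.0
    - 474.0
    - 475.0
    - 476.0
    - 477.0
    - 478.0
    - 479.0
    - 480.0
    - 481.0
    - 482.0
    - 483.0
    - 484.0
    - 485.0
    - 486.0
    - 487.0
    - 488.0
    - 489.0
    - 490.0
    - 491.0
    - 492.0
    - 493.0
    - 494.0
    - 495.0
    - 496.0
    - 497.0
    - 498.0
    - 499.0
    - 500.0
    - 501.0
    - 502.0
    - 503.0
    - 504.0
    - 505.0
    - 506.0
    - 507.0
    - 508.0
    - 509.0
    - 510.0
    - 511.0
    - 512.0
    - 513.0
    - 514.0
    - 515.0
    - 516.0
    - 517.0
    - 518.0
    - 519.0
    - 520.0
    - 521.0
    - 522.0
    - 523.0
    - 524.0
    - 525.0
    - 526.0
    - 527.0
    - 528.0
    - 529.0
    - 530.0
    - 531.0
    - 532.0
    - 533.0
    - 534.0
    - 535.0
    - 536.0
    - 537.0
    - 538.0
    - 539.0
    - 540.0
    - 541.0
    - 542.0
    - 543.0
    - 544.0
    - 545.0
    - 546.0
    - 547.0
    - 548.0
    - 549.0
    - 550.0
    - 551.0
    - 552.0
    - 553.0
    - 554.0
    - 555.0
    - 556.0
    - 557.0
    - 558.0
    - 559.0
    - 560.0
    - 561.0
    - 562.0
    - 563.0
    - 564.0
    - 565.0
    - 566.0
    - 567.0
    - 568.0
    - 569.0
    - 570.0
    - 571.0
    - 572.0
    - 573.0
    - 574.0
    - 575.0
    - 576.0
    - 577.0
    - 578.0
    - 579.0
    - 580.0
    - 581.0
    - 582.0
    - 583.0
    - 584.0
    - 585.0
    - 586.0
    - 587.0
    - 588.0
    - 589.0
    - 590.0
    - 591.0
    - 592.0
    - 593.0
    - 594.0
    - 595.0
    - 596.0
    - 597.0
    - 598.0
    - 599.0
    - 600.0
    peak_nm: 470.0
    width_nm: 40.0
    amp: 1000.0
    wt_exposure: 1.0
    mut_exposure: 1.8
    corrected_exposure: 1.0
    noise_frac: 0.02
    reps: 3.0
  dose_concs_mM:
  - 0.0
  - 0.05
  - 0.1
  - 0.2
  - 0.5
  viability_concs_mM:
  - 0.01
  - 0.05
  - 0.1
  - 0.2
  - 0.5
  viability:
    control_abs: 1.0
    reps: 3.0
    noise_sd: 0.0
  efflux:
    total_cpm: 200000.0
    basal_frac: 0.04
    wt_net_frac: 0.08
    mutant_net_ratio: 0.65
    reps: 3.0
    noise_sd: 0.0
  itc:
    cell_vol_ul: 350.0
    cell_conc_uM: 10.0
    inj_vol_ul: 1.0
    n_inj: 50.0
    dilution_heat: -2.0
    noise_sd: 0.0
seed: 1905
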