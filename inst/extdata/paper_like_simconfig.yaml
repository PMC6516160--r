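n_per_sex_per_site: 615.0
sites:
  TJL: 1.0
  UM: 0.75
  UT: 1.0
cohorts:
- 2004
- 2005
- 2006
- 2007
- 2008
- 2009
gompertz_a: 8.036473087743894e-05
gompertz_b: 0.004
hr_peak_age_days: 350.0
hr_peak_ratio: 2.2
hr_convergence_age_days: 800.0
weaning_age_days: 21.0
cage_size_m: 3.0
cage_size_f: 4.0
cage_censor_prob_m: 0.06
admin_censor_age_days: ~
weight_model:
  mu_asymptote_f_g: 32.0
  mu_asymptote_m_g: 42.0
  growth_rate_k: 0.012
  frailty_weight_coupling_f: 0.8
  frailty_weight_coupling_m: 1.5
  terminal_loss_fraction: 0.1
  terminal_window_days: 90.0
  measurement_noise_sd_g: 1.5
frailty_hazard_coupling:
  F: 0.2
  M: 0.2
seed: 1
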