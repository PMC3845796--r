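# Go/Explore/NoGo and utility parameters, light-object lift study
# (control and PD ON medication).
control:
  lambda_g: 1.53
  lambda_n: -7.18
  sigma_e: 1.00
  a_g: 0.01
  a_n: 1.60
  a_e: 0.43
  alpha: 0.70
  delta_lim: 1.00
  delta_med: 0.00
pd_on:
  lambda_g: 1.53
  lambda_n: -7.18
  sigma_e: 1.00
  a_g: 0.01
  a_n: 1.60
  a_e: 0.43
  alpha: 0.312
  delta_lim: -0.5
  delta_med: 0.427
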