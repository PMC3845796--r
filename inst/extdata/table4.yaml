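# Go/Explore/NoGo and utility parameters, medication/surface study
# (control, PD OFF, PD ON; shared by silk and sandpaper surfaces).
control:
  lambda_g: 1.53
  lambda_n: -7.18
  sigma_e: 1.00
  a_g: 0.60
  a_n: 2.16
  a_e: 0.29
  alpha: 0.50
  delta_lim: 1.00
  delta_med: 0.00
pd_off:
  lambda_g: 1.53
  lambda_n: -7.18
  sigma_e: 1.00
  a_g: 0.60
  a_n: 2.16
  a_e: 0.29
  alpha: 0.30
  delta_lim: 0.5
  delta_med: 0.00
pd_on:
  lambda_g: 1.53
  lambda_n: -7.18
  sigma_e: 1.00
  a_g: 0.60
  a_n: 2.16
  a_e: 0.29
  alpha: 0.30
  delta_lim: 0.5
  delta_med: 0.005
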