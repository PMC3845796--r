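# Experimental condition registry: object mass, friction coefficient and
# grip-reference noise half-width, plus the patient groups simulated.
ingvarsson_silk:
  mass_kg: 0.30
  mu: 0.44
  nu_range_n: 3.0
  groups: [control, pd_off, pd_on]
ingvarsson_sandpaper:
  mass_kg: 0.30
  mu: 0.94
  nu_range_n: 1.5
  groups: [control, pd_off, pd_on]
fellows:
  mass_kg: 0.33
  mu: 0.44
  nu_range_n: 3.0
  groups: [control, pd_on]
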