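# Example scenario description (synthetic). Omitted blocks fall back to
# the packaged succession scenario defaults.
name: succession_example
reactor:
  working_volume: 4.5      # L
  hrt: 6.25                # days
  influent_nh4_load: 86.4  # mg N/day
  do_setpoint: 0.2         # mg O2/L
  temperature: 30          # degrees C
  ph: 7.6
  duration: 56             # days
  seed: 1
disturbance:
  day: 0
  mixing_fraction: 1.0
emission:
  depth: 35000             # reads per sample
  dispersion: 300          # Dirichlet concentration
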