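# Example simulation configuration: desk-scale run of a fibrotic valve.
# Unspecified entries fall back to the reference defaults.
fluid:
  grid_n: [16, 16, 48]
numerics:
  dt: 4.0e-5
  cycles: 2
  struct_resolution: 0.06
pressure:
  amplitude: 0.5
  P0: 4.0
  P0_ramp: 0.3
scenario: fibrotic
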