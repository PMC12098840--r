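# Six-coil 20 cm behavioural arena with its evaluation cylinders.
seed: 1
grid_mm: 1
array:
  preset: arena20
regions:
  h5:  {shape: cylinder, radius_m: 0.10, height_m: 0.05}
  h10: {shape: cylinder, radius_m: 0.10, height_m: 0.10}
  h15: {shape: cylinder, radius_m: 0.10, height_m: 0.15}
  h20: {shape: cylinder, radius_m: 0.10, height_m: 0.20}
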