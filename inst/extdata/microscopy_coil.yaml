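# Single-coil on-microscope stimulation apparatus with its central
# evaluation region (2 cm axial x 2 cm diametral).
seed: 1
grid_mm: 1
coil:
  preset: microscopy
regions:
  center:
    shape: cylinder
    radius_m: 0.01
    height_m: 0.02
protocol:
  channel_count: 1
  phases:
    - {stim_s: 30, rest_s: 30, frequency_hz: 10, dead_time_s: 0.001,
       mode: bidirectional, repeats: 5}
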