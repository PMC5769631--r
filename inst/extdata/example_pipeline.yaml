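# Example valvemorph pipeline configuration.
# Stages run in dependency order; all randomness flows from the root seed
# passed to run_pipeline().
pipeline:
  stages: [signal, simulate, decompose]

geometry:
  length: 8
  avc_half_width: 0.4

motion:
  # two-chamber pump preset; replace with `table: [[x, a, phi], ...]`
  # to supply measured amplitude/phase profiles
  chamber_amplitude: [0.35, 0.5]
  avc_amplitude: 0.25
  avc_phase: 0.3
  dphi: 2.2
  f1: 1

membrane:
  k_s: 5
  k_b: 0.01
  n_nodes: 24

simulate:
  n_rbc: 0
  n_per_wall: 64
  steps_per_beat: 60
  n_beats: 4
  discard_beats: 2
  samples_per_beat: 30
  n_stations: 32

decompose:
  harmonics: 3
  side: upper

signal:
  constant: 2
  harmonics:
    - [1, 3.0, 0.0]
    - [2, 0.5, 0.0]
  n_beats: 8
  samples_per_beat: 64
  noise_sd: 0.25
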