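# Demo pipeline configuration: small synthetic run of all four stages.
# Runs in well under five minutes on one CPU and is fully deterministic
# given `seed`.
stages:
  - texture
  - tracks
  - ddct
  - matrisome
seed: 20260101
texture:
  image_size: 96
  images_per_level: 2
  kappas: [0, 2, 8]
  target_coverage: 0.25
  mean_orientation: 30
tracks:
  n_tracks: 60
  duration: 12
  frame_interval: 5
  max_lag: 48
  conditions:
    - name: control
      class_proportions: [0.50, 0.20, 0.30]
    - name: fibrotic
      class_proportions: [0.55, 0.30, 0.15]
ddct:
  housekeeping: [ACTB, B2M, RPLP0]
  n_per_group: 3
  ct_noise_sd: 0.2
  group_delta_ct_shift:
    WH01: -2.5
    WH02: 2.0
    WH03: -1.5
matrisome:
  n_proteins: 150
  n_per_group: 3
  dispersion: 0.3
  matrisome_fraction: 0.3
  log2_effect:
    P0001: 3.0
    P0002: -3.0
    P0003: 2.5
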