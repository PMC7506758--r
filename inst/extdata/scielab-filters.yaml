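# Opponent decomposition and HVS contrast-sensitivity filter parameters for
# the spatial CIELAB pipeline. One Gaussian term per list entry:
#   weight        relative amplitude (may be negative for surround lobes)
#   halfwidth_deg Gaussian spread in degrees of visual angle; the realized
#                 pixel-domain sigma is halfwidth_deg * samples_per_degree.
# The summed per-channel kernel is renormalized to unit sum at realization.
version: 1
opponent_matrix:   # rows map (X, Y, Z) -> (O1 luminance, O2 red-green, O3 blue-yellow)
  - [0.279, 0.72, -0.107]
  - [-0.449, 0.29, -0.077]
  - [0.086, -0.59, 0.501]
filters:
  luminance:
    - {weight: 0.921, halfwidth_deg: 0.0283}
    - {weight: 0.105, halfwidth_deg: 0.133}
    - {weight: -0.108, halfwidth_deg: 4.336}
  red_green:
    - {weight: 0.531, halfwidth_deg: 0.0392}
    - {weight: 0.330, halfwidth_deg: 0.494}
  blue_yellow:
    - {weight: 0.488, halfwidth_deg: 0.0536}
    - {weight: 0.371, halfwidth_deg: 0.386}
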