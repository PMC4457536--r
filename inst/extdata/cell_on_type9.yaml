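cell_type: ON_type9
target_compartments: 94
soma_diameter: 11.0
region_layout:
- region: dendrite
  z_extent: 15.0
  n_branches: 6
  n_compartments: 36
  diameter: 0.9
  spread: 12.0
- region: axon
  z_extent: 60.0
  n_branches: 1
  n_compartments: 34
  diameter: 1.2
  spread: 0.0
- region: terminal
  z_extent: 12.0
  n_branches: 4
  n_compartments: 23
  diameter: 1.2
  spread: 8.0
depth_sigma_fraction: 0.15
seed: 1
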