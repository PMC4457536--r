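cell_type: OFF_type3
target_compartments: 78
soma_diameter: 9.0
region_layout:
- region: dendrite
  z_extent: 14.0
  n_branches: 6
  n_compartments: 30
  diameter: 0.9
  spread: 11.0
- region: axon
  z_extent: 22.0
  n_branches: 1
  n_compartments: 12
  diameter: 1.2
  spread: 0.0
- region: terminal
  z_extent: 10.0
  n_branches: 5
  n_compartments: 35
  diameter: 1.2
  spread: 9.0
depth_sigma_fraction: 0.15
seed: 1
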