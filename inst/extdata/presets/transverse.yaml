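# Transverse diaphyseal fracture: 43 mm femoral section, 6 mm gap,
# 11 mm intramedullary nail, 1 mm voxels.
geometry:
  outer_radius: 15
  cortical_thickness: 5.25
  periosteum_thickness: 1
  nail_diameter: 11
  length: 43
  voxel: 1
  margin: 7
fracture:
  kind: transverse
  gap: 6
boundary:
  mode: regions
  c_high: 1.0
  c_low: 0.3
  scale: 0.16
time:
  dt: 0.25
  horizon: 100
  stop_at_closure: true
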