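# Comminuted diaphyseal fracture: a transverse cut combined with a
# 30 degree oblique cut (3 mm gaps); the bone between the two cuts is the
# inert intermediate fragment (no concentration, no cell production -- a
# bridging substrate only). Same section and calibration as the transverse
# preset.
geometry:
  outer_radius: 15
  cortical_thickness: 5.25
  periosteum_thickness: 1
  nail_diameter: 11
  length: 43
  voxel: 1
  margin: 7
fracture:
  kind: comminuted
  gap: 3
  slope_deg: 30
  offset: 6.5
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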