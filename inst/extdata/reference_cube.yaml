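name: reference-cube
prism:
  length_m: 1.5
  width_m: 1.5
  height_m: 1.5
material: concrete
roughness_factor_vertical: 1.0
slab_height_m: 0.0
bulk_density_kg_m3: 2400.0
through_holes: []
nest_cavities:
- diameter_m: 0.3
  depth_m: 0.3
  face: north
  center:
  - -0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: north
  center:
  - 0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: south
  center:
  - -0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: south
  center:
  - 0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: east
  center:
  - -0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: east
  center:
  - 0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: west
  center:
  - -0.4
  - 0.0
- diameter_m: 0.3
  depth_m: 0.3
  face: west
  center:
  - 0.4
  - 0.0
material_ph: 7.5
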