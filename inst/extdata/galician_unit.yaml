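name: galician-estuary-unit
prism:
  length_m: 1.5
  width_m: 1.5
  height_m: 1.5
material: concrete
roughness_factor_vertical: 1.0
slab_height_m: 0.0
bulk_density_kg_m3: 2400.0
through_holes:
- diameter_m: 0.6
  orientation: vertical_top
  face: top
  connects_to: interior_cavity
  depth_m: 1.0
  roughness_factor: 1.0
  center:
  - 0.0
  - 0.0
- diameter_m: 0.25
  orientation: horizontal_lateral
  face: north
  connects_to: interior_cavity
  depth_m: 0.45
  roughness_factor: 1.0
  center:
  - 0.0
  - 0.0
- diameter_m: 0.45
  orientation: horizontal_lateral
  face: east
  connects_to: interior_cavity
  depth_m: 0.45
  roughness_factor: 1.0
  center:
  - 0.0
  - 0.0
nest_cavities:
- diameter_m: 0.2
  depth_m: 0.2
  face: north
  center:
  - -0.5
  - -0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: north
  center:
  - -0.5
  - 0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: north
  center:
  - 0.5
  - 0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: north
  center:
  - 0.5
  - -0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: north
  center:
  - 0.0
  - -0.52
- diameter_m: 0.2
  depth_m: 0.2
  face: south
  center:
  - -0.5
  - -0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: south
  center:
  - -0.5
  - 0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: south
  center:
  - 0.5
  - 0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: south
  center:
  - 0.5
  - -0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: south
  center:
  - 0.0
  - -0.52
- diameter_m: 0.2
  depth_m: 0.2
  face: east
  center:
  - -0.5
  - -0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: east
  center:
  - -0.5
  - 0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: east
  center:
  - 0.5
  - 0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: east
  center:
  - 0.5
  - -0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: east
  center:
  - 0.0
  - -0.52
- diameter_m: 0.2
  depth_m: 0.2
  face: west
  center:
  - -0.5
  - -0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: west
  center:
  - -0.5
  - 0.4
- diameter_m: 0.2
  depth_m: 0.2
  face: west
  center:
  - 0.5
  - 0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: west
  center:
  - 0.5
  - -0.4
- diameter_m: 0.3
  depth_m: 0.3
  face: west
  center:
  - 0.0
  - -0.52
material_ph: 7.5
mass_t: 5.0
surface_overrides:
  weighted_exposed_cm2: 68835.0
  upwelling_cm2: 107750.0
  nest_cavity_cm2: 9423.0
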