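---
title: "Scoring and stability-checking artificial-reef unit designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and stability-checking artificial-reef unit designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefscore)
```

## The model

An artificial-reef (AR) unit raises the productivity of a fishing ground
through three pathways: more sunlit substrate for primary producers
(energy), more vertical surface generating upwelling and back eddies that
circulate nutrients, and more blind cavities for shelter and recruitment
(habitat). `reefscore` quantifies each pathway as a ratio between a
candidate design and a reference design of the same bounding volume, and
sums the three ratios — optionally weighted — into a single comparative
score. A self-comparison scores exactly 3 with unit weights; the score is
dimensionless, relative, and meaningful only between designs occupying the
same volume (the package warns when bounding volumes differ by more than
5%).

The three partial indices consume a *surface inventory* derived from the
parametric description of the unit: a rectangular prism with cylindrical
through-holes (an upper central hole opening into an interior cavity,
and/or lateral holes) and blind cylindrical nest cavities.

```{r}
reference <- reference_cube()
final <- galician_unit()
areit_index(final, reference)
```

## Surface-accounting conventions

The inventory rules are the load-bearing modelling decisions, so they are
explicit and (where genuinely ambiguous) configurable through
`inventory_conventions()`:

- **Nest cavities count by opening disc area** (`pi d^2/4`), not interior
  wall area, and their openings are **not** subtracted from the host face.
  Both choices are pinned by the reference cube: eight 30 cm cavities give
  5,655 cm² only under opening-disc accounting, and the reference sums
  90,000 / 67,500 cm² are only reproduced without subtraction (the cavity
  replaces flat substrate with an equal-or-larger curved one; the index
  books the opening once, on the habitat axis).
- **The seabed-contact face and the ballast slab carry no area**: neither
  is biologically active.
- **Through-hole openings are subtracted** from their host faces (they
  remove substrate), and the upper central cavity contributes its
  cylindrical wall to the vertical total and its floor disc to the
  horizontal total — it exists precisely to collect sunlight and nutrients
  inside. Both behaviours are flags because the published sums for the
  final worked-example design (68,835 and 107,750 cm²) cannot be
  reconstructed from its published geometry: the hole-per-face roster and
  cavity depths of that design are under-specified. The shipped fixture
  therefore carries those sums as explicit `surface_overrides`, which take
  precedence in index computations, while the geometry-derived values stay
  available (`galician_unit(use_table_overrides = FALSE)`). The habitat
  index needs no override: the cavity rosters alone give 1.67.
- **A lateral hole into the central cavity breaches two walls** (exterior
  plus cavity wall) and by default contributes one opening per wall to the
  upwelling discount; `lateral_hole_walls = "per_hole"` books a single
  opening, since the governing sum is defined only over "the lateral
  holes".
- Areas are carried in cm², lengths in metres, with the conversion at the
  inventory boundary; rosters large enough to matter are always sums of
  exact disc areas, so no precision is lost.

Inclined planes (the only non-prismatic geometry supported) interpolate
their exposure factor between the horizontal value 1 at 0° and the
vertical value 0.5 at 90°, and their upwelling factor between 0 and 1.
Linear interpolation in the angle is the default; a sine model is
available. Only the endpoints and monotonicity are constrained by the
underlying framework, so the interpolant is a documented package choice.
When a through-hole pierces an inclined plane, the plane's contribution is
multiplied by its upwelling factor and the hole openings are subtracted
with the factor of their host plane; the two extensions are never combined
in the source framework, so this composition is likewise a package choice.

## Rounding

Display reports round each partial half-up to two decimals *before*
summing (`rounding = "paper"`): 1.02 + 1.20 + 1.67 = 3.89, although the
full-precision partials sum to 3.88. Programmatic comparison and ranking
always use `rounding = "full"` so that ordering never depends on display
rounding. `compare_designs()` breaks exact ties alphabetically by name.

Undefined partials raise errors rather than returning 0 or infinity: the
index is only defined against references that themselves contribute to
every compared dimension (a reference without nest cavities cannot anchor
the habitat ratio). Setting a weight to zero skips that dimension and its
preconditions entirely, supporting nutrient-only or energy-plus-habitat
comparisons.

## The stability procedure

The stability module implements the simplest of the assessment routes for
a preliminary desk study: no wave propagation modelling and no CFD, just a
design wave from site sea-state parameters, an analytic wave theory for
the kinematics, and the Morison force balance.

- **Design wave**: `H_max = H_s * sqrt(ln(N)/2)`, the Rayleigh most
  probable maximum of an `N`-wave sea state (default `N = 1000`, roughly a
  3-hour storm; `H_s = 5.5` m maps to `H_max = 10.2` m), capped by the
  depth-limited breaking criterion `gamma h` with `gamma = 0.78`.
- **Theory selection**: the Ursell number `H L^2 / h^3` decides between
  linear (Airy) theory and first-order cnoidal theory (threshold 26). The
  wavelength comes from the linear dispersion relation, solved by Newton
  iteration to a relative residual below 1e-12.
- **Cnoidal kinematics**: the elliptic parameter `m` is solved from
  `(H, T, h)` by coupling the Ursell relation `Ur = 16 m K(m)^2 / 3` with
  the first-order celerity `c^2 = g h [1 + (H/(m h))(2 - m - 3E/K)]`,
  iterating `L = cT` to convergence (the celerity limits to the solitary
  wave `c^2 = g(h + H)` as `m` approaches 1 and the profile to a sinusoid
  as `m` approaches 0). The first-order horizontal velocity is
  depth-uniform, `u = c eta / h`. Outside the cnoidal validity range the
  parameter solve reports the offending Ursell number rather than
  extrapolating.
- **Forces**: Morison drag plus inertia with defaults `C_D = 1.05`,
  `C_M = 2.0` for a cubic block, friction `mu = 0.6` for concrete on sand,
  zero lift unless a lift coefficient is supplied — all exposed in
  `stability_coefficients()` because every one of them is an empirical,
  site-specific choice. A steady current is superposed on the orbital
  velocity in the drag term; full wave–current interaction modelling is
  out of scope. Kinematics are evaluated at mid-height of the unit by
  default, with an optional strip integration (`n_strips`) for tall
  configurations.
- **Safety factors**: sliding `mu (W_sub - F_lift) / F_h` and overturning
  (restoring over overturning moment about the downstream bottom edge),
  both at the phase of maximum total force over a swept cycle.
  `size_slab()` scans slab heights at a configurable resolution (0.05 m
  default) and returns the smallest height meeting both targets; the slab
  plan area defaults to the unit footprint and is configurable, since the
  source framework does not fix it. Note that a footprint-sized slab also
  adds frontal area, so for sufficiently severe waves no slab height is
  stabilising — the error names the limiting failure mode, which is the
  correct engineering answer (the unit needs a different foundation, not a
  taller slab). No published force or safety-factor values exist for the
  worked example, so the stability module is verified purely by its
  analytic structure: dispersion residuals, the cnoidal-to-linear and
  solitary limits, Morison parity/linearity, and the inverse consistency
  of slab sizing against the stability check.

```{r}
conds <- wave_conditions(hs = 1.6, tp = 10, depth = 9)
wave <- design_wave(conds)
stability_check(final, wave, conds)
size_slab(final, wave, conds)
```

## The synthetic design generator

`random_design()` draws cubic units with edge 1.0–2.5 m, up to three
lateral holes (0.15–0.45 m), up to twelve nest cavities (0.10–0.35 m) and
an upper central hole with probability one half — ranges bracketing the
1.5 m worked-example unit, which is the scale actually deployed in
estuarine enhancement. Openings are placed by rejection sampling until
non-overlapping; identical seeds give identical designs. Lateral holes
connect to the central cavity when one exists and bore through to the
opposite face otherwise, so every generated design is physically coherent.

The generator emulates the *geometry* of real designs, not their ecology:
passing tests show that the accounting, validation and index machinery is
correct over a broad design population, not that any generated design
would perform well in the sea. Real units differ in ways the generator
ignores — non-cubic bases, suspension holes, material finishes, biofouling
over time — and cavity depth (defaulted to one diameter) never enters the
index under opening-disc accounting.

## Numerical choices and limitations

- Disc overlap validation uses exact centre-distance tests with a 1e-12 m
  slack; overlapping openings are reported, never silently merged.
- Surface areas are validated in tests against an independent discretised
  oracle (grid indicator integration for plane faces, fine polygonal
  approximation for cylinders) to 0.5%.
- The dispersion Newton iteration is guarded by an Eckart-type initial
  guess and converges in under ten iterations over periods 2–25 s and
  depths 1–200 m; hyperbolic ratios are computed in exponential form to
  avoid overflow in deep water.
- The elliptic-parameter bracket is `[1e-15, 1 - 1e-15]`; extreme solitary
  limits beyond `m = 1 - 1e-15` (Ursell numbers in the thousands) are not
  representable in double precision and raise rather than degrade.
- Problem sizes in the shipped tests (a 1,000-design validity sweep,
  twenty mesh-oracle designs of ~360k grid cells per face, 721-phase force
  sweeps) were chosen so the full suite characterises the machinery well
  while running in seconds.
- The index is comparative only: it predicts nothing absolute about
  biomass, and economic, social and structural criteria (stress limits on
  hole counts, manufacture, transport) are outside its scope and must be
  imposed as constraints by the designer.
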