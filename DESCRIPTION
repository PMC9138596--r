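Package: reefscore
Title: Ecosystem-Ecology Scoring and Wave-Loading Stability of Artificial Reef Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and comparing modular artificial-reef (AR)
    units from an ecosystem-ecology perspective. Describes a reef unit as a
    parametric rectangular prism with cylindrical through-holes and blind nest
    cavities, derives its exposed-surface inventory, and scores candidate
    designs against a reference of equal volume with a comparative index built
    from three partial indices: energy modification (sunlit substrate area),
    nutrient modification (upwelling-generating vertical surface, discounted
    for lateral holes) and habitat modification (nest-cavity opening area).
    Includes a qualitative design checklist, multi-design ranking with a
    three-axis graphical comparison, and a simplified wave-loading stability
    procedure: design-wave estimation from a sea state, linear (Airy) and
    first-order cnoidal kinematics, Morison force evaluation, sliding and
    overturning safety factors, and sizing of a ballast slab.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
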