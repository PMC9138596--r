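# scale every linear dimension of a design by c (areas scale as c^2)
scale_design <- function(design, c) {
  design$length <- design$length * c
  design$width <- design$width * c
  design$height <- design$height * c
  design$slab_height <- design$slab_height * c
  design$through_holes <- lapply(design$through_holes, function(h) {
    h$diameter <- h$diameter * c
    h$depth <- h$depth * c
    h$center <- h$center * c
    h
  })
  design$nest_cavities <- lapply(design$nest_cavities, function(nc) {
    nc$diameter <- nc$diameter * c
    nc$depth <- nc$depth * c
    nc$center <- nc$center * c
    nc
  })
  design$inclined_panels <- lapply(design$inclined_panels, function(p) {
    p$area_m2 <- p$area_m2 * c^2
    p
  })
  design
}

# bare cube of edge a with two 30 cm cavities per vertical face (a valid
# index reference)
simple_reference <- function(a = 1.5) {
  cav <- list()
  for (f in c("north", "south", "east", "west")) {
    cav <- c(cav, list(nest_cavity(0.2 * a, depth = 0.2 * a, face = f,
                                   center = c(-0.25 * a, 0)),
                       nest_cavity(0.2 * a, depth = 0.2 * a, face = f,
                                   center = c(0.25 * a, 0))))
  }
  ar_unit_design(name = sprintf("cube-%g", a), length = a, width = a,
                 height = a, nest_cavities = cav)
}
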