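# Independent discretised-surface oracles. These never call the analytic
# accounting path: plane faces are integrated on a fine grid of cell
# indicators, cylinders and discs are approximated by many-sided polygons.

# area (m2) of a w x h rectangle minus circular openings, by grid sampling
oracle_plane_area <- function(w, h, discs = list(), n = 600) {
  u <- seq(-w / 2 + w / (2 * n), w / 2 - w / (2 * n), length.out = n)
  v <- seq(-h / 2 + h / (2 * n), h / 2 - h / (2 * n), length.out = n)
  gu <- matrix(u, n, n)
  gv <- matrix(v, n, n, byrow = TRUE)
  inside_hole <- matrix(FALSE, n, n)
  for (d in discs) {
    inside_hole <- inside_hole |
      ((gu - d$center[1])^2 + (gv - d$center[2])^2 < d$r^2)
  }
  mean(!inside_hole) * w * h
}

# lateral area (m2) of a cylinder of diameter d and height hgt via an
# n-sided prism
oracle_cylinder_wall <- function(d, hgt, n = 4096) {
  n * d * sin(pi / n) * hgt
}

polygon_disc <- function(d, n = 4096) {
  # area between inscribed and circumscribed n-gons, averaged
  r <- d / 2
  inscribed <- 0.5 * n * r^2 * sin(2 * pi / n)
  circumscribed <- n * r^2 * tan(pi / n)
  (inscribed + circumscribed) / 2
}

# full surface-inventory oracle under the default conventions
oracle_inventory <- function(design) {
  m2 <- 1e4
  discs_on <- function(face) {
    out <- list()
    for (h in design$through_holes) {
      if (h$orientation == "horizontal_lateral") {
        if (h$face == face)
          out <- c(out, list(list(center = h$center, r = h$diameter / 2)))
        if (h$connects_to == "opposite_face") {
          opp <- c(north = "south", south = "north", east = "west",
                   west = "east")[h$face]
          if (identical(unname(opp), face))
            out <- c(out, list(list(center = h$center, r = h$diameter / 2)))
        }
      }
    }
    out
  }
  S_v <- 0
  for (f in c("north", "south")) {
    S_v <- S_v + oracle_plane_area(design$length, design$height, discs_on(f))
  }
  for (f in c("east", "west")) {
    S_v <- S_v + oracle_plane_area(design$width, design$height, discs_on(f))
  }
  central <- Filter(function(h) h$orientation == "vertical_top",
                    design$through_holes)
  laterals_in <- Filter(function(h)
    h$orientation == "horizontal_lateral" && h$connects_to == "interior_cavity",
    design$through_holes)
  top_discs <- lapply(central, function(h)
    list(center = h$center, r = h$diameter / 2))
  S_h <- oracle_plane_area(design$length, design$width, top_discs)
  for (h in central) {
    wall <- oracle_cylinder_wall(h$diameter, h$depth)
    for (lh in laterals_in) wall <- wall - polygon_disc(lh$diameter)
    S_v <- S_v + max(0, wall)
    if (h$connects_to == "interior_cavity")
      S_h <- S_h + polygon_disc(h$diameter)  # cavity floor
  }
  nests <- vapply(design$nest_cavities,
                  function(nc) polygon_disc(nc$diameter) * m2, numeric(1))
  list(S_v_cm2 = S_v * m2, S_h_cm2 = S_h * m2,
       nest_cavity_areas_cm2 = nests)
}

# bisection solver for the linear dispersion relation, independent of the
# package's Newton iteration
oracle_dispersion <- function(period, depth, g = 9.81) {
  omega <- 2 * pi / period
  f <- function(L) {
    k <- 2 * pi / L
    g * k * tanh(k * depth) - omega^2
  }
  lo <- 1e-3
  hi <- 1.6 * g * period^2  # beyond the deep-water wavelength
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
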