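#' Reference reef unit: the basic 1.5 m cube
#'
#' The baseline design used as the comparison reference: a 1.5 m concrete
#' cube with no through-holes and eight 30 cm nest cavities distributed two
#' per vertical face. Its surface inventory reproduces the published
#' reference sums: vertical area 90,000 cm2, weighted sunlit sum 67,500 cm2
#' and cavity opening area 5,655 cm2 (nearest cm2).
#'
#' @return An `ar_unit_design`.
#' @export
reference_cube <- function() {
  cavities <- list()
  for (face in VERTICAL_FACES) {
    cavities <- c(cavities, list(
      nest_cavity(0.30, depth = 0.30, face = face, center = c(-0.40, 0)),
      nest_cavity(0.30, depth = 0.30, face = face, center = c(0.40, 0))))
  }
  ar_unit_design(
    name = "reference-cube",
    length = 1.5, width = 1.5, height = 1.5,
    nest_cavities = cavities,
    material = "concrete", material_ph = 7.5,
    roughness_factor_vertical = 1)
}

# symmetric per-face layout for the estuary unit: three 20 cm and two 30 cm
# cavities around a central lateral hole; centres chosen non-overlapping,
# they do not affect any index value
galician_face_cavities <- function(face) {
  list(
    nest_cavity(0.20, depth = 0.20, face = face, center = c(-0.50, -0.40)),
    nest_cavity(0.20, depth = 0.20, face = face, center = c(-0.50, 0.40)),
    nest_cavity(0.20, depth = 0.20, face = face, center = c(0.50, 0.40)),
    nest_cavity(0.30, depth = 0.30, face = face, center = c(0.50, -0.40)),
    nest_cavity(0.30, depth = 0.30, face = face, center = c(0.00, -0.52)))
}

#' Final reef unit designed for Galician estuaries
#'
#' A 1.5 m cube with a 600 mm upper central hole opening into an interior
#' cavity, two lateral holes (250 and 450 mm) connecting the exterior with
#' that cavity, and twenty nest cavities (twelve of 20 cm, eight of 30 cm)
#' distributed over the four vertical faces. Exact cavity centres are not
#' part of the published description; a documented symmetric layout is used
#' (centres affect validation only, never an index value). Each lateral hole
#' pierces one exterior wall.
#'
#' The published surface sums for this design (weighted sunlit 68,835 cm2,
#' upwelling 107,750 cm2, cavity 9,423 cm2) cannot be reconstructed exactly
#' from the published geometry, whose hole-per-face roster and cavity depths
#' are under-specified. With `use_table_overrides = TRUE` (default) those
#' sums are injected verbatim and take precedence in index computations; the
#' geometry-derived values remain available through the inventory.
#'
#' @param use_table_overrides Inject the published surface sums.
#' @return An `ar_unit_design`.
#' @export
galician_unit <- function(use_table_overrides = TRUE) {
  cavities <- do.call(c, lapply(VERTICAL_FACES, galician_face_cavities))
  holes <- list(
    through_hole(0.60, orientation = "vertical_top", face = "top",
                 connects_to = "interior_cavity", depth = 1.0,
                 roughness_factor = 1, center = c(0, 0)),
    through_hole(0.25, orientation = "horizontal_lateral", face = "north",
                 connects_to = "interior_cavity", depth = 0.45,
                 roughness_factor = 1, center = c(0, 0)),
    through_hole(0.45, orientation = "horizontal_lateral", face = "east",
                 connects_to = "interior_cavity", depth = 0.45,
                 roughness_factor = 1, center = c(0, 0)))
  overrides <- if (use_table_overrides) {
    list(weighted_exposed_cm2 = 68835,
         upwelling_cm2 = 107750,
         nest_cavity_cm2 = 9423)
  } else NULL
  ar_unit_design(
    name = "galician-estuary-unit",
    length = 1.5, width = 1.5, height = 1.5,
    through_holes = holes,
    nest_cavities = cavities,
    material = "concrete", material_ph = 7.5,
    roughness_factor_vertical = 1,
    mass_t = 5,
    surface_overrides = overrides)
}

#' Parameter ranges for the random design generator
#'
#' @param edge Range of cube edge lengths, metres.
#' @param hole_diameter Range of lateral-hole diameters, metres.
#' @param n_lateral_holes Integer range of lateral-hole counts.
#' @param cavity_diameter Range of nest-cavity diameters, metres.
#' @param n_cavities Integer range of nest-cavity counts.
#' @param p_central_hole Probability of an upper central hole.
#' @param max_rejections Placement attempts per opening before giving up.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(edge = c(1.0, 2.5),
                           hole_diameter = c(0.15, 0.45),
                           n_lateral_holes = c(0L, 3L),
                           cavity_diameter = c(0.10, 0.35),
                           n_cavities = c(0L, 12L),
                           p_central_hole = 0.5,
                           max_rejections = 200L) {
  stopifnot(edge[2] > edge[1], hole_diameter[2] > hole_diameter[1],
            cavity_diameter[2] > cavity_diameter[1],
            p_central_hole >= 0, p_central_hole <= 1)
  structure(list(edge = edge, hole_diameter = hole_diameter,
                 n_lateral_holes = as.integer(n_lateral_holes),
                 cavity_diameter = as.integer(0) + cavity_diameter,
                 n_cavities = as.integer(n_cavities),
                 p_central_hole = p_central_hole,
                 max_rejections = as.integer(max_rejections)),
            class = "generator_spec")
}

# rejection-sample a centre for a disc of radius r on a face already holding
# `placed` discs (list of list(center, r)); NULL when the budget is exhausted
place_disc <- function(dims, r, placed, max_rejections) {
  half_u <- dims[1] / 2 - r
  half_v <- dims[2] / 2 - r
  if (half_u <= 0 || half_v <= 0) return(NULL)
  for (i in seq_len(max_rejections)) {
    center <- c(stats::runif(1, -half_u, half_u),
                stats::runif(1, -half_v, half_v))
    ok <- all(vapply(placed, function(p)
      sqrt(sum((p$center - center)^2)) >= p$r + r + 1e-6, logical(1)))
    if (ok) return(center)
  }
  NULL
}

#' Generate a random valid reef-unit design
#'
#' Draws a cubic design within the spec's ranges, placing openings by
#' rejection sampling until non-overlapping. Identical seeds produce
#' identical designs; every generated design passes [validate_design()].
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed (uses the current RNG state when `NULL`).
#' @param name Design name.
#' @return An `ar_unit_design`.
#' @export
random_design <- function(spec = generator_spec(), seed = NULL,
                          name = "random-design") {
  if (!is.null(seed)) set.seed(seed)
  edge <- stats::runif(1, spec$edge[1], spec$edge[2])
  placed <- stats::setNames(vector("list", length(FACES)), FACES)
  holes <- list()
  cavities <- list()

  has_central <- stats::runif(1) < spec$p_central_hole
  if (has_central) {
    d <- stats::runif(1, spec$hole_diameter[1],
                      min(spec$hole_diameter[2], 0.6 * edge))
    holes <- c(holes, list(through_hole(
      d, orientation = "vertical_top", face = "top",
      connects_to = "interior_cavity",
      depth = stats::runif(1, 0.3, 0.8) * edge,
      roughness_factor = 1, center = c(0, 0))))
    placed$top <- list(list(center = c(0, 0), r = d / 2))
  }

  # lateral holes bore into the central cavity when one exists, otherwise
  # straight through to the opposite face
  n_lh <- sample(spec$n_lateral_holes[1]:spec$n_lateral_holes[2], 1)
  for (i in seq_len(n_lh)) {
    face <- sample(VERTICAL_FACES, 1)
    d <- stats::runif(1, spec$hole_diameter[1],
                      min(spec$hole_diameter[2], 0.5 * edge))
    ctr <- place_disc(c(edge, edge), d / 2, placed[[face]],
                      spec$max_rejections)
    if (is.null(ctr))
      stop("opening placement failed after ", spec$max_rejections,
           " rejections; loosen the generator ranges", call. = FALSE)
    holes <- c(holes, list(through_hole(
      d, orientation = "horizontal_lateral", face = face,
      connects_to = if (has_central) "interior_cavity" else "opposite_face",
      depth = if (has_central) stats::runif(1, 0.2, 0.45) * edge else edge,
      roughness_factor = 1, center = ctr)))
    placed[[face]] <- c(placed[[face]], list(list(center = ctr, r = d / 2)))
  }

  n_nc <- sample(spec$n_cavities[1]:spec$n_cavities[2], 1)
  for (j in seq_len(n_nc)) {
    d <- stats::runif(1, spec$cavity_diameter[1],
                      min(spec$cavity_diameter[2], 0.4 * edge))
    ctr <- NULL
    # try faces in random order so one crowded face cannot sink the draw
    for (face in sample(VERTICAL_FACES)) {
      ctr <- place_disc(c(edge, edge), d / 2, placed[[face]],
                        spec$max_rejections)
      if (!is.null(ctr)) break
    }
    if (is.null(ctr))
      stop("opening placement failed after ", spec$max_rejections,
           " rejections per face; loosen the generator ranges",
           call. = FALSE)
    cavities <- c(cavities, list(nest_cavity(
      d, depth = min(d, 0.4 * edge), face = face, center = ctr)))
    placed[[face]] <- c(placed[[face]], list(list(center = ctr, r = d / 2)))
  }

  ar_unit_design(name = name, length = edge, width = edge, height = edge,
                 through_holes = holes, nest_cavities = cavities,
                 material = "concrete",
                 roughness_factor_vertical = 1)
}

#' Paths of the shipped fixture design files
#'
#' @return Named character vector of YAML file paths installed with the
#'   package.
#' @export
fixture_paths <- function() {
  dir <- system.file("extdata", package = "reefscore")
  c(reference = file.path(dir, "reference_cube.yaml"),
    galician = file.path(dir, "galician_unit.yaml"))
}
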