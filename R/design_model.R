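#' @importFrom stats setNames
NULL

FACES <- c("top", "bottom", "north", "south", "east", "west")
VERTICAL_FACES <- c("north", "south", "east", "west")

#' Describe a cylindrical through-hole
#'
#' A through-hole connects two spaces of the reef unit: either an exterior
#' face with the interior cavity, or two opposite exterior faces. The upper
#' central hole is a special case: a vertical bore in the top face whose
#' interior cavity collects sunlight and receives nutrients.
#'
#' @param diameter Hole diameter in metres.
#' @param orientation `"vertical_top"` for the upper central hole,
#'   `"horizontal_lateral"` for a lateral hole in a vertical face.
#' @param face Host face, one of `top`, `north`, `south`, `east`, `west`.
#' @param connects_to `"interior_cavity"` or `"opposite_face"`.
#' @param depth Bore depth in metres, measured from the host face along the
#'   hole axis. For the upper central hole this is the cavity depth.
#' @param roughness_factor Dimensionless roughness factor of the hole
#'   opening used in the upwelling-surface discount.
#' @param center Opening centre on the host face, local `(u, v)` coordinates
#'   in metres with origin at the face centre.
#' @return A `reef_hole` list.
#' @export
through_hole <- function(diameter,
                         orientation = c("horizontal_lateral", "vertical_top"),
                         face,
                         connects_to = c("interior_cavity", "opposite_face"),
                         depth,
                         roughness_factor = 1,
                         center = c(0, 0)) {
  orientation <- match.arg(orientation)
  connects_to <- match.arg(connects_to)
  structure(list(
    diameter = as.numeric(diameter),
    orientation = orientation,
    face = face,
    connects_to = connects_to,
    depth = as.numeric(depth),
    roughness_factor = as.numeric(roughness_factor),
    center = as.numeric(center)
  ), class = "reef_hole")
}

#' Describe a blind nest cavity
#'
#' Nest cavities are blind cylindrical holes (or surface indentations) that
#' provide shelter; they never connect two spaces of the unit. Their opening
#' disc area is what enters the habitat-modification index.
#'
#' @param diameter Cavity diameter in metres.
#' @param depth Cavity depth in metres; defaults to one diameter.
#' @param face Host face label.
#' @param center Opening centre `(u, v)` on the host face, metres.
#' @return A `reef_cavity` list.
#' @export
nest_cavity <- function(diameter, depth = diameter, face, center = c(0, 0)) {
  structure(list(
    diameter = as.numeric(diameter),
    depth = as.numeric(depth),
    face = face,
    center = as.numeric(center)
  ), class = "reef_cavity")
}

#' Parametric description of one artificial-reef unit
#'
#' The unit is a rectangular prism (usually a cube) pierced by cylindrical
#' through-holes and dotted with blind nest cavities, optionally sitting on a
#' ballast slab. The slab serves stability only and contributes no biological
#' surface. All lengths are metres; surface accounting converts to cm2 at the
#' inventory boundary.
#'
#' @param name Design label, used in reports and rankings.
#' @param length,width,height Edge lengths of the base prism in metres.
#' @param through_holes List of [through_hole()] objects.
#' @param nest_cavities List of [nest_cavity()] objects.
#' @param material Material label (informational, feeds the checklist).
#' @param material_ph Declared surface pH of the cured material (optional;
#'   checked against the seawater-compatible band 7.4-7.6 by the checklist).
#' @param roughness_factor_vertical Roughness factor of the vertical
#'   surfaces (dimensionless, default 1 for smooth formed concrete).
#' @param slab_height Ballast slab height in metres (0 = no slab).
#' @param mass_t Unit mass in tonnes (optional, informational; when absent
#'   the stability module derives mass from the solid prism volume and
#'   `bulk_density`).
#' @param bulk_density Material bulk density in kg/m3 (default concrete).
#' @param inclined_panels Optional list of inclined planar surfaces, each a
#'   list with `area_m2` and `angle_deg` (degrees from horizontal).
#' @param surface_overrides Optional list injecting externally measured
#'   surface sums (cm2): `weighted_exposed_cm2`, `upwelling_cm2`,
#'   `nest_cavity_cm2`. When present they take precedence over the
#'   geometry-derived sums in index computations; the geometric values are
#'   still reported alongside.
#' @return An `ar_unit_design` object.
#' @seealso [validate_design()], [compute_surface_inventory()]
#' @export
ar_unit_design <- function(name,
                           length, width, height,
                           through_holes = list(),
                           nest_cavities = list(),
                           material = "concrete",
                           material_ph = NA_real_,
                           roughness_factor_vertical = 1,
                           slab_height = 0,
                           mass_t = NA_real_,
                           bulk_density = 2400,
                           inclined_panels = list(),
                           surface_overrides = NULL) {
  structure(list(
    name = as.character(name),
    length = as.numeric(length),
    width = as.numeric(width),
    height = as.numeric(height),
    through_holes = through_holes,
    nest_cavities = nest_cavities,
    material = as.character(material),
    material_ph = as.numeric(material_ph),
    roughness_factor_vertical = as.numeric(roughness_factor_vertical),
    slab_height = as.numeric(slab_height),
    mass_t = as.numeric(mass_t),
    bulk_density = as.numeric(bulk_density),
    inclined_panels = inclined_panels,
    surface_overrides = surface_overrides
  ), class = "ar_unit_design")
}

#' @export
print.ar_unit_design <- function(x, ...) {
  cat(sprintf("<ar_unit_design> %s: %.2f x %.2f x %.2f m prism\n",
              x$name, x$length, x$width, x$height))
  cat(sprintf("  %d through-hole(s), %d nest cavities, slab %.2f m, material %s\n",
              length(x$through_holes), length(x$nest_cavities),
              x$slab_height, x$material))
  if (!is.null(x$surface_overrides))
    cat("  surface overrides present (take precedence in index computations)\n")
  invisible(x)
}

# face rectangle (u, v) extents in metres for a given design
face_dims <- function(design, face) {
  switch(face,
    top = ,
    bottom = c(design$length, design$width),
    north = ,
    south = c(design$length, design$height),
    east = ,
    west = c(design$width, design$height),
    stop("unknown face: ", face)
  )
}

# prism dimension along the axis normal to a face (bore-depth bound)
axis_dim <- function(design, face) {
  switch(face,
    top = ,
    bottom = design$height,
    north = ,
    south = design$width,
    east = ,
    west = design$length,
    stop("unknown face: ", face)
  )
}

#' Validate a reef-unit design
#'
#' Checks the geometric invariants of an [ar_unit_design()]: positive
#' dimensions, every opening disc fully inside its host face, no two
#' openings on the same face overlapping, bore depths within the prism, and
#' nest cavities blind (strictly shallower than the wall they sit in).
#'
#' @param design An `ar_unit_design`.
#' @return Character vector of human-readable violations; empty when the
#'   design is valid. Violations are returned, never raised.
#' @export
validate_design <- function(design) {
  v <- character()
  for (f in c("length", "width", "height")) {
    if (!is.finite(design[[f]]) || design[[f]] <= 0)
      v <- c(v, sprintf("%s: must be a positive length, got %s", f, design[[f]]))
  }
  if (!is.finite(design$slab_height) || design$slab_height < 0)
    v <- c(v, sprintf("slab_height: must be >= 0, got %s", design$slab_height))
  if (!is.finite(design$roughness_factor_vertical) ||
      design$roughness_factor_vertical <= 0)
    v <- c(v, "roughness_factor_vertical: must be > 0")
  if (length(v) > 0) return(v)  # face checks need sane dimensions

  openings <- list()  # per-face registry for overlap checks
  register <- function(face, center, radius, label) {
    openings[[face]] <<- c(openings[[face]],
                           list(list(center = center, r = radius, label = label)))
  }

  for (i in seq_along(design$through_holes)) {
    h <- design$through_holes[[i]]
    lab <- sprintf("through_holes[%d]", i)
    if (!is.finite(h$diameter) || h$diameter <= 0) {
      v <- c(v, sprintf("%s$diameter: must be > 0, got %s", lab, h$diameter))
      next
    }
    if (!h$face %in% setdiff(FACES, "bottom"))
      v <- c(v, sprintf("%s$face: '%s' is not a usable host face", lab, h$face))
    if (h$orientation == "vertical_top" && h$face != "top")
      v <- c(v, sprintf("%s: a vertical_top hole must sit on the top face", lab))
    if (h$orientation == "horizontal_lateral" && !h$face %in% VERTICAL_FACES)
      v <- c(v, sprintf("%s: a horizontal_lateral hole needs a vertical host face", lab))
    if (!is.finite(h$depth) || h$depth <= 0)
      v <- c(v, sprintf("%s$depth: must be > 0, got %s", lab, h$depth))
    else if (h$face %in% FACES && h$depth > axis_dim(design, h$face) + 1e-12)
      v <- c(v, sprintf("%s$depth: %.3f m exceeds the %.3f m prism dimension along its axis",
                        lab, h$depth, axis_dim(design, h$face)))
    if (h$face %in% FACES) {
      dims <- face_dims(design, h$face)
      r <- h$diameter / 2
      if (abs(h$center[1]) + r > dims[1] / 2 + 1e-12 ||
          abs(h$center[2]) + r > dims[2] / 2 + 1e-12)
        v <- c(v, sprintf("%s: opening exceeds face '%s' (disc of radius %.3f m at (%.2f, %.2f))",
                          lab, h$face, r, h$center[1], h$center[2]))
      else register(h$face, h$center, r, lab)
    }
  }

  for (j in seq_along(design$nest_cavities)) {
    nc <- design$nest_cavities[[j]]
    lab <- sprintf("nest_cavities[%d]", j)
    if (!is.finite(nc$diameter) || nc$diameter <= 0) {
      v <- c(v, sprintf("%s$diameter: must be > 0, got %s", lab, nc$diameter))
      next
    }
    if (!is.finite(nc$depth) || nc$depth <= 0)
      v <- c(v, sprintf("%s$depth: must be > 0, got %s", lab, nc$depth))
    if (!nc$face %in% FACES) {
      v <- c(v, sprintf("%s$face: unknown face '%s'", lab, nc$face))
      next
    }
    if (is.finite(nc$depth) && nc$depth >= axis_dim(design, nc$face))
      v <- c(v, sprintf("%s: depth %.3f m pierces the %.3f m wall; nest cavities are blind",
                        lab, nc$depth, axis_dim(design, nc$face)))
    dims <- face_dims(design, nc$face)
    r <- nc$diameter / 2
    if (abs(nc$center[1]) + r > dims[1] / 2 + 1e-12 ||
        abs(nc$center[2]) + r > dims[2] / 2 + 1e-12)
      v <- c(v, sprintf("%s: opening exceeds face '%s'", lab, nc$face))
    else register(nc$face, nc$center, r, lab)
  }

  # pairwise disc-overlap test per face
  for (face in names(openings)) {
    os <- openings[[face]]
    if (length(os) < 2) next
    for (a in seq_len(length(os) - 1)) {
      for (b in seq(a + 1, length(os))) {
        d <- sqrt(sum((os[[a]]$center - os[[b]]$center)^2))
        if (d < os[[a]]$r + os[[b]]$r - 1e-12)
          v <- c(v, sprintf("face '%s': openings %s and %s overlap (centres %.3f m apart, radii sum %.3f m)",
                            face, os[[a]]$label, os[[b]]$label,
                            d, os[[a]]$r + os[[b]]$r))
      }
    }
  }
  v
}

stop_if_invalid <- function(design) {
  v <- validate_design(design)
  if (length(v) > 0)
    stop("invalid design '", design$name, "':\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)
  invisible(design)
}

#' Surface-accounting conventions
#'
#' The published reference sums pin down most of the accounting (nest-cavity
#' openings are not subtracted from faces; the seabed-contact face and the
#' slab carry no area), but two behaviours are left configurable because the
#' source geometry under-determines them.
#'
#' @param subtract_hole_openings Subtract through-hole opening discs from
#'   their host faces (they remove substrate). Default `TRUE`.
#' @param include_cavity_interior Count the upper central cavity's
#'   cylindrical wall as vertical area and its floor disc as horizontal
#'   area. Default `TRUE`.
#' @param lateral_hole_walls `"per_wall"`: a lateral hole piercing into the
#'   central cavity contributes one opening per wall breached (exterior wall
#'   plus cavity wall); `"per_hole"`: a single opening per hole.
#' @return A named list of conventions.
#' @export
inventory_conventions <- function(subtract_hole_openings = TRUE,
                                  include_cavity_interior = TRUE,
                                  lateral_hole_walls = c("per_wall", "per_hole")) {
  list(subtract_hole_openings = isTRUE(subtract_hole_openings),
       include_cavity_interior = isTRUE(include_cavity_interior),
       lateral_hole_walls = match.arg(lateral_hole_walls))
}

disc_area_m2 <- function(diameter) pi * diameter^2 / 4

#' Compute the exposed-surface inventory of a design
#'
#' Derives, in cm2, the areas the comparative index consumes: total vertical
#' exposed area `S_v` (external faces plus the interior cavity wall, minus
#' through-hole openings), total horizontal exposed area `S_h` (top face
#' minus the central-hole opening, plus the cavity floor), per-hole lateral
#' opening areas with their roughness factors, per-cavity opening disc
#' areas, and any inclined panels. The seabed-contact face and the ballast
#' slab are excluded throughout; nest-cavity openings are never subtracted
#' from their host faces.
#'
#' @param design A valid `ar_unit_design`.
#' @param conventions An [inventory_conventions()] list.
#' @return A `reef_inventory` object: list with `S_v_cm2`, `S_h_cm2`,
#'   `lateral_holes` (data frame of `area_cm2`, `roughness`),
#'   `nest_cavity_areas_cm2`, `inclined` (data frame of `area_cm2`,
#'   `angle_deg`), `overrides`, `conventions`, `bounding_volume_m3`.
#' @export
compute_surface_inventory <- function(design,
                                      conventions = inventory_conventions()) {
  stop_if_invalid(design)
  M2_TO_CM2 <- 1e4

  S_v <- 2 * (design$length + design$width) * design$height  # 4 external walls, m2
  S_h <- design$length * design$width                        # top face, m2
  lateral <- data.frame(area_cm2 = numeric(), roughness = numeric(),
                        hole = character())
  cavity_wall_area <- 0

  central <- Filter(function(h) h$orientation == "vertical_top",
                    design$through_holes)
  laterals <- Filter(function(h) h$orientation == "horizontal_lateral",
                     design$through_holes)

  for (h in central) {
    open_a <- disc_area_m2(h$diameter)
    if (conventions$subtract_hole_openings) S_h <- S_h - open_a
    if (conventions$include_cavity_interior) {
      cavity_wall_area <- cavity_wall_area + pi * h$diameter * h$depth
      if (h$connects_to == "interior_cavity") S_h <- S_h + open_a  # cavity floor disc
    }
  }

  for (i in seq_along(laterals)) {
    h <- laterals[[i]]
    open_a <- disc_area_m2(h$diameter)
    if (conventions$subtract_hole_openings) {
      S_v <- S_v - open_a                          # exterior wall opening
      if (h$connects_to == "opposite_face") S_v <- S_v - open_a
      if (h$connects_to == "interior_cavity" &&
          conventions$include_cavity_interior &&
          cavity_wall_area > 0)
        cavity_wall_area <- max(0, cavity_wall_area - open_a)
    }
    n_walls <- if (conventions$lateral_hole_walls == "per_wall") 2L else 1L
    lateral <- rbind(lateral, data.frame(
      area_cm2 = rep(open_a * M2_TO_CM2, n_walls),
      roughness = rep(h$roughness_factor, n_walls),
      hole = sprintf("lateral_%d%s", i,
                     if (n_walls == 2L) c("_outer", "_inner") else "")))
  }

  S_v <- S_v + cavity_wall_area

  nests <- vapply(design$nest_cavities,
                  function(nc) disc_area_m2(nc$diameter) * M2_TO_CM2,
                  numeric(1))

  inclined <- if (length(design$inclined_panels) > 0) {
    data.frame(
      area_cm2 = vapply(design$inclined_panels,
                        function(p) p$area_m2 * M2_TO_CM2, numeric(1)),
      angle_deg = vapply(design$inclined_panels,
                         function(p) p$angle_deg, numeric(1)))
  } else data.frame(area_cm2 = numeric(), angle_deg = numeric())

  structure(list(
    design_name = design$name,
    S_v_cm2 = S_v * M2_TO_CM2,
    S_h_cm2 = S_h * M2_TO_CM2,
    roughness_factor_vertical = design$roughness_factor_vertical,
    lateral_holes = lateral,
    nest_cavity_areas_cm2 = nests,
    inclined = inclined,
    overrides = design$surface_overrides,
    conventions = conventions,
    bounding_volume_m3 = design$length * design$width * design$height
  ), class = "reef_inventory")
}

#' @export
print.reef_inventory <- function(x, ...) {
  cat(sprintf("<reef_inventory> %s\n", x$design_name))
  cat(sprintf("  S_v = %.0f cm2, S_h = %.0f cm2\n", x$S_v_cm2, x$S_h_cm2))
  cat(sprintf("  lateral-hole openings: %d (%.0f cm2), nest cavities: %d (%.0f cm2)\n",
              nrow(x$lateral_holes), sum(x$lateral_holes$area_cm2),
              length(x$nest_cavity_areas_cm2), sum(x$nest_cavity_areas_cm2)))
  if (!is.null(x$overrides))
    cat("  surface overrides present\n")
  invisible(x)
}

#' Export an inventory as a tidy table
#'
#' One row per surface element with its area, class and the factor that
#' weights it in the index.
#'
#' @param inv A `reef_inventory`.
#' @return Data frame with columns `element`, `class`, `area_cm2`, `factor`.
#' @export
inventory_table <- function(inv) {
  rows <- list(
    data.frame(element = "vertical_total", class = "vertical",
               area_cm2 = inv$S_v_cm2, factor = inv$roughness_factor_vertical),
    data.frame(element = "horizontal_total", class = "horizontal",
               area_cm2 = inv$S_h_cm2, factor = 1))
  if (nrow(inv$lateral_holes) > 0)
    rows <- c(rows, list(data.frame(
      element = inv$lateral_holes$hole, class = "lateral_hole",
      area_cm2 = inv$lateral_holes$area_cm2,
      factor = inv$lateral_holes$roughness)))
  if (length(inv$nest_cavity_areas_cm2) > 0)
    rows <- c(rows, list(data.frame(
      element = sprintf("nest_cavity_%d", seq_along(inv$nest_cavity_areas_cm2)),
      class = "nest_cavity", area_cm2 = inv$nest_cavity_areas_cm2,
      factor = 1)))
  if (nrow(inv$inclined) > 0)
    rows <- c(rows, list(data.frame(
      element = sprintf("inclined_%d", seq_len(nrow(inv$inclined))),
      class = "inclined", area_cm2 = inv$inclined$area_cm2,
      factor = inv$inclined$angle_deg)))
  do.call(rbind, rows)
}

# ---- design file I/O --------------------------------------------------------

design_to_list <- function(design) {
  out <- list(
    name = design$name,
    prism = list(length_m = design$length, width_m = design$width,
                 height_m = design$height),
    material = design$material,
    roughness_factor_vertical = design$roughness_factor_vertical,
    slab_height_m = design$slab_height,
    bulk_density_kg_m3 = design$bulk_density,
    through_holes = lapply(design$through_holes, function(h)
      list(diameter_m = h$diameter, orientation = h$orientation,
           face = h$face, connects_to = h$connects_to, depth_m = h$depth,
           roughness_factor = h$roughness_factor,
           center = as.list(h$center))),
    nest_cavities = lapply(design$nest_cavities, function(nc)
      list(diameter_m = nc$diameter, depth_m = nc$depth, face = nc$face,
           center = as.list(nc$center))))
  if (is.finite(design$material_ph)) out$material_ph <- design$material_ph
  if (is.finite(design$mass_t)) out$mass_t <- design$mass_t
  if (length(design$inclined_panels) > 0)
    out$inclined_panels <- lapply(design$inclined_panels, function(p)
      list(area_m2 = p$area_m2, angle_deg = p$angle_deg))
  if (!is.null(design$surface_overrides))
    out$surface_overrides <- design$surface_overrides
  out
}

require_keys <- function(x, keys, where) {
  miss <- setdiff(keys, names(x))
  if (length(miss) > 0)
    stop("design file schema: missing ", paste(miss, collapse = ", "),
         " in ", where, call. = FALSE)
}

design_from_list <- function(raw, where = "design") {
  require_keys(raw, c("name", "prism"), where)
  require_keys(raw$prism, c("length_m", "width_m", "height_m"),
               paste0(where, "$prism"))
  holes <- lapply(seq_along(raw$through_holes), function(i) {
    h <- raw$through_holes[[i]]
    require_keys(h, c("diameter_m", "orientation", "face", "connects_to",
                      "depth_m"), sprintf("%s$through_holes[%d]", where, i))
    through_hole(diameter = h$diameter_m, orientation = h$orientation,
                 face = h$face, connects_to = h$connects_to,
                 depth = h$depth_m,
                 roughness_factor = h$roughness_factor %||% 1,
                 center = unlist(h$center %||% list(0, 0)))
  })
  cavities <- lapply(seq_along(raw$nest_cavities), function(j) {
    nc <- raw$nest_cavities[[j]]
    require_keys(nc, c("diameter_m", "face"),
                 sprintf("%s$nest_cavities[%d]", where, j))
    nest_cavity(diameter = nc$diameter_m,
                depth = nc$depth_m %||% nc$diameter_m,
                face = nc$face, center = unlist(nc$center %||% list(0, 0)))
  })
  inclined <- lapply(raw$inclined_panels, function(p)
    list(area_m2 = p$area_m2, angle_deg = p$angle_deg))
  ar_unit_design(
    name = raw$name,
    length = raw$prism$length_m, width = raw$prism$width_m,
    height = raw$prism$height_m,
    through_holes = holes, nest_cavities = cavities,
    material = raw$material %||% "concrete",
    material_ph = raw$material_ph %||% NA_real_,
    roughness_factor_vertical = raw$roughness_factor_vertical %||% 1,
    slab_height = raw$slab_height_m %||% 0,
    mass_t = raw$mass_t %||% NA_real_,
    bulk_density = raw$bulk_density_kg_m3 %||% 2400,
    inclined_panels = inclined,
    surface_overrides = raw$surface_overrides)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a reef-unit design file
#'
#' Designs are stored one per file as YAML (JSON accepted, selected by the
#' `.json` extension) with top-level keys `name`, `prism`, `through_holes`,
#' `nest_cavities` plus optional factors, slab and override fields. The file
#' is schema-checked and the resulting design validated; violations raise an
#' error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` design file.
#' @return An `ar_unit_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("cannot parse design file ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  design <- design_from_list(raw, where = basename(path))
  stop_if_invalid(design)
  design
}

#' Write a reef-unit design file
#'
#' @param design An `ar_unit_design`.
#' @param path Destination; `.json` selects JSON, anything else YAML.
#'   Writing then reading reproduces an equal design.
#' @return `path`, invisibly.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  lst <- design_to_list(design)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}
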