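# Qualitative impact signs of the design determinants on the four ecosystem
# dimensions (substrate availability, light supply, nutrient supply, habitat
# for settling individuals). Static encoding; "+" positive, "-" negative,
# NA no impact.
CHECKLIST_SIGNS <- data.frame(
  determinant = c("material_type", "material_ph", "roughness", "area",
                  "verticality", "upper_central_hole", "lateral_holes",
                  "nest_cavity_size", "nest_cavity_type",
                  "nest_cavity_number"),
  energy_substrate = c("+", "+", "+", "+", "+", NA, "-", NA, NA, NA),
  energy_light     = c(NA, NA, NA, NA, "-", "+", NA, NA, NA, NA),
  nutrients        = c(NA, NA, NA, NA, "+", NA, "+", NA, NA, NA),
  habitat          = c(NA, NA, NA, "+", NA, NA, NA, "+", "+", "+"),
  stringsAsFactors = FALSE)

#' Qualitative design checklist
#'
#' Audits a design against the determinant factors known to drive fish
#' biomass on artificial reefs: material (type, surface pH, roughness),
#' area, verticality, the upper central hole, lateral holes and the nest
#' cavities (size, type, number). Each determinant carries a static sign
#' pattern describing which ecosystem dimension it helps or hurts (for
#' example, lateral holes cost substrate but aid nutrient circulation).
#'
#' @param design An `ar_unit_design`.
#' @return Data frame with one row per determinant: `determinant`, `status`
#'   (`present` / `absent` / `not-evaluable`), `note`, and the four signed
#'   impact columns.
#' @export
meem_checklist <- function(design) {
  stop_if_invalid(design)
  has_central <- any(vapply(design$through_holes,
                            function(h) h$orientation == "vertical_top",
                            logical(1)))
  n_lateral <- sum(vapply(design$through_holes,
                          function(h) h$orientation == "horizontal_lateral",
                          logical(1)))
  n_cav <- length(design$nest_cavities)
  ph <- design$material_ph

  status <- c(
    material_type = if (nzchar(design$material)) "present" else "not-evaluable",
    material_ph = if (!is.finite(ph)) "not-evaluable"
                  else if (ph >= 7.4 && ph <= 7.6) "present" else "absent",
    roughness = "present",
    area = "present",
    verticality = "present",
    upper_central_hole = if (has_central) "present" else "absent",
    lateral_holes = if (n_lateral > 0) "present" else "absent",
    nest_cavity_size = if (n_cav > 0) "present" else "absent",
    nest_cavity_type = if (n_cav > 0) "present" else "absent",
    nest_cavity_number = if (n_cav > 0) "present" else "absent")

  note <- c(
    material_type = design$material,
    material_ph = if (is.finite(ph)) {
      sprintf("declared pH %.2f (%s the seawater-compatible band 7.4-7.6)",
              ph, if (status["material_ph"] == "present") "within" else "outside")
    } else "no pH declared",
    roughness = sprintf("vertical roughness factor %.2f",
                        design$roughness_factor_vertical),
    area = sprintf("prism %.2f x %.2f x %.2f m",
                   design$length, design$width, design$height),
    verticality = "4 vertical faces",
    upper_central_hole = if (has_central) "upper central hole present"
                         else "no upper central hole",
    lateral_holes = sprintf("%d lateral hole(s)", n_lateral),
    nest_cavity_size = if (n_cav > 0) {
      sprintf("diameters %s m", paste(sort(unique(vapply(
        design$nest_cavities, function(nc) nc$diameter, numeric(1)))),
        collapse = ", "))
    } else "none",
    nest_cavity_type = if (n_cav > 0) "blind cylindrical cavities" else "none",
    nest_cavity_number = sprintf("%d nest cavities", n_cav))

  out <- CHECKLIST_SIGNS
  out$status <- unname(status[out$determinant])
  out$note <- unname(note[out$determinant])
  out[, c("determinant", "status", "note", "energy_substrate",
          "energy_light", "nutrients", "habitat")]
}

#' Score and rank candidate designs against a reference
#'
#' Evaluates every candidate with the comparative index (full-precision
#' partials, so ranking never depends on display rounding) and ranks them,
#' ties broken by name. Candidates whose bounding volume differs from the
#' reference by more than 5% are flagged: the index compares impact per
#' unit of occupied volume.
#'
#' @param reference An `ar_unit_design`.
#' @param candidates List of `ar_unit_design` objects.
#' @param factors A [factor_set()].
#' @param conventions An [inventory_conventions()] list.
#' @return A `comparison_set`: list with `reference`, `reports` (one
#'   `areit_report` per candidate, full rounding), and `ranking` (data
#'   frame: rank, design, EM, NM, HM, AREIT, volume_flag).
#' @export
compare_designs <- function(reference, candidates, factors = factor_set(),
                            conventions = inventory_conventions()) {
  if (length(candidates) == 0) stop("no candidate designs", call. = FALSE)
  ref_inv <- compute_surface_inventory(reference, conventions)
  reports <- lapply(candidates, function(cand) {
    tryCatch(
      areit_index(cand, ref_inv, factors, rounding = "full",
                  conventions = conventions, check_volume = FALSE),
      error = function(e) stop("candidate '", cand$name, "': ",
                               conditionMessage(e), call. = FALSE))
  })
  vols <- vapply(candidates, function(d) d$length * d$width * d$height,
                 numeric(1))
  flag <- abs(vols - ref_inv$bounding_volume_m3) /
    ref_inv$bounding_volume_m3 > 0.05
  ranking <- data.frame(
    design = vapply(reports, function(r) r$candidate, character(1)),
    EM = vapply(reports, function(r) r$EM, numeric(1)),
    NM = vapply(reports, function(r) r$NM, numeric(1)),
    HM = vapply(reports, function(r) r$HM, numeric(1)),
    AREIT = vapply(reports, function(r) r$AREIT, numeric(1)),
    volume_flag = flag,
    stringsAsFactors = FALSE)
  ord <- order(-ranking$AREIT, ranking$design)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  if (any(flag))
    warning("candidate(s) ",
            paste(ranking$design[ranking$volume_flag], collapse = ", "),
            " differ from the reference bounding volume by > 5%",
            call. = FALSE)
  structure(list(reference = reference$name, reports = reports,
                 ranking = ranking[, c("rank", "design", "EM", "NM", "HM",
                                       "AREIT", "volume_flag")]),
            class = "comparison_set")
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set> vs reference %s\n", x$reference))
  print(x$ranking, digits = 4)
  invisible(x)
}

# oblique projection of (x, y, z) index space onto the page
project3d <- function(x, y, z) {
  list(px = x - 0.45 * y, py = z - 0.45 * y * 0.6)
}

#' Three-axis graphical comparison of partial indices
#'
#' Draws the three orthogonal index axes (energy, nutrient and habitat
#' modification) and, for each design, the triangle through its three axis
#' intercepts. The reference plane (intercepts 1, 1, 1) is always drawn; a
#' candidate whose triangle lies outside it improves every dimension.
#'
#' @param comparison A `comparison_set` from [compare_designs()].
#' @param path Output image path (`.png` or `.svg` by extension).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
plot_index_planes <- function(comparison, path, width = 7, height = 6) {
  if (length(comparison$reports) == 0)
    stop("no designs to plot", call. = FALSE)
  partials <- lapply(comparison$reports, function(r) c(r$EM, r$NM, r$HM))
  if (any(!is.finite(unlist(partials))))
    stop("every design needs three finite partial indices to be plotted",
         call. = FALSE)

  open_dev <- function(p) {
    if (grepl("\\.svg$", p, ignore.case = TRUE))
      grDevices::svg(p, width = width, height = height)
    else grDevices::png(p, width = width * 100, height = height * 100,
                        res = 100)
  }
  ok <- tryCatch({ open_dev(path); TRUE },
                 error = function(e) stop("cannot write figure to ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  on.exit(grDevices::dev.off(), add = TRUE)

  lim <- max(1, unlist(partials)) * 1.25
  axis_pts <- project3d(c(lim, 0, 0), c(0, lim, 0), c(0, 0, lim))
  all_x <- c(0, axis_pts$px); all_y <- c(0, axis_pts$py)
  graphics::plot(NA, xlim = range(all_x) + c(-0.2, 0.2),
                 ylim = range(all_y) + c(-0.2, 0.2),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = "Partial-index planes vs reference")
  org <- project3d(0, 0, 0)
  for (i in 1:3) {
    graphics::segments(org$px, org$py, axis_pts$px[i], axis_pts$py[i],
                       lwd = 1.5, col = "grey30")
  }
  lab <- c("EM (energy)", "NM (nutrients)", "HM (habitat)")
  graphics::text(axis_pts$px, axis_pts$py, lab, pos = c(4, 1, 3), cex = 0.9)

  cols <- grDevices::hcl.colors(max(3, length(partials) + 1), "Dark 3")
  draw_plane <- function(p, col, lty = 1, lwd = 2) {
    tri <- project3d(c(p[1], 0, 0), c(0, p[2], 0), c(0, 0, p[3]))
    graphics::polygon(tri$px, tri$py,
                      border = col, lwd = lwd, lty = lty,
                      col = grDevices::adjustcolor(col, alpha.f = 0.15))
    graphics::points(tri$px, tri$py, pch = 19, col = col, cex = 0.8)
  }
  draw_plane(c(1, 1, 1), "grey40", lty = 2)
  for (i in seq_along(partials)) draw_plane(partials[[i]], cols[i])
  graphics::legend("topright", bty = "n", cex = 0.85,
                   legend = c(sprintf("reference %s (1, 1, 1)",
                                      comparison$reference),
                              vapply(comparison$reports, function(r)
                                sprintf("%s (%.2f, %.2f, %.2f)", r$candidate,
                                        r$EM, r$NM, r$HM), character(1))),
                   col = c("grey40", cols[seq_along(partials)]),
                   lty = c(2, rep(1, length(partials))), lwd = 2)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full design framework on design files
#'
#' Executes the three framework stages in order: the qualitative checklist
#' for every design, the comparative-index ranking of the candidates
#' against the reference, and (when sea-state conditions are supplied) the
#' wave-loading stability check with slab sizing for the top-ranked
#' candidate (or all of them). All outputs land in `out_dir` with a
#' machine-readable JSON manifest and a plain-text log; with fixed inputs
#' and seed the machine-readable outputs are bit-identical across runs.
#'
#' @param reference_path Path to the reference design file.
#' @param candidate_paths Character vector of candidate design files.
#' @param out_dir Output directory (created if missing).
#' @param factors A [factor_set()].
#' @param conventions An [inventory_conventions()] list.
#' @param conditions Optional [wave_conditions()]; `NULL` skips stability.
#' @param coefficients A [stability_coefficients()].
#' @param targets Safety-factor targets for slab sizing.
#' @param all_stability Run stability on every candidate, not only the
#'   top-ranked one.
#' @param rounding Rounding mode for the reported comparison block.
#' @param seed Integer seed fixed at entry for reproducibility.
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_framework <- function(reference_path, candidate_paths, out_dir,
                          factors = factor_set(),
                          conventions = inventory_conventions(),
                          conditions = NULL,
                          coefficients = stability_coefficients(),
                          targets = c(sliding = 1.2, overturning = 1.2),
                          all_stability = FALSE,
                          rounding = "paper",
                          seed = 1L) {
  set.seed(seed)
  for (p in c(reference_path, candidate_paths))
    if (!file.exists(p)) stop("design file not found: ", p, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  say("stage checklist: reading %d design file(s)", 1 + length(candidate_paths))
  reference <- run_stage("checklist", read_design(reference_path))
  candidates <- run_stage("checklist", lapply(candidate_paths, read_design))

  checklists <- run_stage("checklist", {
    cl <- lapply(c(list(reference), candidates), function(d)
      cbind(design = d$name, meem_checklist(d)))
    do.call(rbind, cl)
  })
  checklist_csv <- file.path(out_dir, "checklist.csv")
  utils::write.csv(checklists, checklist_csv, row.names = FALSE)
  say("stage checklist: wrote %s", basename(checklist_csv))

  comparison <- run_stage("comparison",
                          compare_designs(reference, candidates, factors,
                                          conventions))
  ranking_csv <- file.path(out_dir, "ranking.csv")
  utils::write.csv(comparison$ranking, ranking_csv, row.names = FALSE)
  plot_path <- NULL
  if (all(factors$weights > 0)) {  # a subset run has no three-axis plane
    plot_path <- file.path(out_dir, "index_planes.png")
    run_stage("comparison", plot_index_planes(comparison, plot_path))
  }
  say("stage comparison: top-ranked design %s", comparison$ranking$design[1])

  # display-rounded reports for the manifest comparison block
  display <- lapply(candidates, function(cand)
    areit_index(cand, reference, factors, rounding = rounding,
                conventions = conventions, check_volume = FALSE))

  stability <- NULL
  if (!is.null(conditions)) {
    wave <- run_stage("stability", design_wave(conditions))
    todo <- if (all_stability) seq_along(candidates)
            else match(comparison$ranking$design[1],
                       vapply(candidates, function(d) d$name, character(1)))
    stability <- lapply(todo, function(i) {
      d <- candidates[[i]]
      rep <- run_stage("stability",
                       stability_check(d, wave, conditions, coefficients))
      slab <- run_stage("stability",
                        size_slab(d, wave, conditions, coefficients, targets))
      say("stage stability: %s needs slab height %.2f m", d$name, slab)
      c(unclass(rep), list(required_slab_m = slab,
                           design_wave = unclass(wave)))
    })
    stab_csv <- file.path(out_dir, "stability.csv")
    utils::write.csv(do.call(rbind, lapply(stability, function(s)
      data.frame(design = s$design, theory = s$theory,
                 horizontal_force_N = s$horizontal_force_N,
                 sliding_sf = s$sliding_sf,
                 overturning_sf = s$overturning_sf,
                 required_slab_m = s$required_slab_m))),
      stab_csv, row.names = FALSE)
    say("stage stability: wrote %s", basename(stab_csv))
  } else {
    say("stage stability: skipped (no sea-state conditions supplied)")
  }

  manifest <- list(
    seed = seed,
    inputs = list(reference = basename(reference_path),
                  candidates = as.list(basename(candidate_paths))),
    outputs = list(checklist = basename(checklist_csv),
                   ranking = basename(ranking_csv),
                   plot = if (is.null(plot_path)) NA else basename(plot_path)),
    comparison = list(
      reference = reference$name,
      rounding = rounding,
      reports = lapply(display, function(r)
        list(candidate = r$candidate, EM = r$EM, NM = r$NM, HM = r$HM,
             AREIT = r$AREIT)),
      ranking = comparison$ranking),
    stability = stability)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}
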