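#' Exposure, roughness and weighting factors for the comparative index
#'
#' @param f_ev Exposure factor for vertical surfaces (default 0.5).
#' @param f_eh Exposure factor for horizontal surfaces (default 1); must be
#'   at least `f_ev` (horizontal substrate collects more sunlight).
#' @param weights Named numeric weights `c(em =, nm =, hm =)` for the three
#'   partial indices; default equal weighting.
#' @param inclined_model `"linear"` or `"sine"`: how the exposure and
#'   upwelling factors of an inclined plane interpolate between their
#'   horizontal and vertical endpoints as a function of the inclination
#'   angle.
#' @return A `factor_set` list.
#' @export
factor_set <- function(f_ev = 0.5, f_eh = 1,
                       weights = c(em = 1, nm = 1, hm = 1),
                       inclined_model = c("linear", "sine")) {
  inclined_model <- match.arg(inclined_model)
  stopifnot(f_ev > 0, f_eh >= f_ev, all(weights >= 0), length(weights) == 3)
  if (is.null(names(weights))) names(weights) <- c("em", "nm", "hm")
  structure(list(f_ev = f_ev, f_eh = f_eh, weights = weights,
                 inclined_model = inclined_model),
            class = "factor_set")
}

check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 90))
    stop("inclination angle must lie in [0, 90] degrees from horizontal",
         call. = FALSE)
  theta
}

#' Exposure factor of an inclined surface
#'
#' Interpolates between the horizontal exposure factor at 0 degrees and the
#' vertical one at 90 degrees, strictly monotone in between. The default is
#' linear in the angle; a sine model is available.
#'
#' @param theta Inclination in degrees from horizontal, in `[0, 90]`.
#' @param factors A [factor_set()].
#' @return Dimensionless exposure factor.
#' @export
inclined_exposure_factor <- function(theta, factors = factor_set()) {
  check_theta(theta)
  frac <- switch(factors$inclined_model,
                 linear = theta / 90,
                 sine = sin(theta * pi / 180))
  factors$f_eh + (factors$f_ev - factors$f_eh) * frac
}

#' Upwelling contribution factor of an inclined surface
#'
#' 0 for a horizontal surface (no upwelling generated), 1 for a vertical
#' one, strictly monotone in between.
#'
#' @inheritParams inclined_exposure_factor
#' @param model `"linear"` or `"sine"`.
#' @return Dimensionless factor in `[0, 1]`.
#' @export
inclined_upwelling_factor <- function(theta, model = c("linear", "sine")) {
  model <- match.arg(model)
  check_theta(theta)
  switch(model, linear = theta / 90, sine = sin(theta * pi / 180))
}

as_inventory <- function(x, conventions = inventory_conventions()) {
  if (inherits(x, "reef_inventory")) x
  else if (inherits(x, "ar_unit_design")) compute_surface_inventory(x, conventions)
  else stop("expected an ar_unit_design or reef_inventory", call. = FALSE)
}

#' Weighted sunlit-surface sum of a design
#'
#' The numerator (or denominator) of the energy-modification index:
#' `S_v * f_ev + S_h * f_eh` plus any inclined panels weighted by their
#' angle-dependent exposure factor. A `weighted_exposed_cm2` override on the
#' inventory takes precedence.
#'
#' @param inv A `reef_inventory` (or design).
#' @param factors A [factor_set()].
#' @return Area-weighted sum in cm2.
#' @export
weighted_exposed_area <- function(inv, factors = factor_set()) {
  inv <- as_inventory(inv)
  ov <- inv$overrides$weighted_exposed_cm2
  if (!is.null(ov)) return(as.numeric(ov))
  s <- inv$S_v_cm2 * factors$f_ev + inv$S_h_cm2 * factors$f_eh
  if (nrow(inv$inclined) > 0)
    s <- s + sum(inv$inclined$area_cm2 *
                   inclined_exposure_factor(inv$inclined$angle_deg, factors))
  s
}

#' Upwelling-generating surface of a design
#'
#' Vertical area weighted by its roughness factor, minus the lateral-hole
#' openings (each weighted by its own roughness factor), plus inclined
#' panels weighted by roughness and the angle-dependent upwelling factor;
#' floored at zero. Nest cavities never enter. An `upwelling_cm2` override
#' takes precedence.
#'
#' @inheritParams weighted_exposed_area
#' @return Upwelling surface in cm2 (>= 0).
#' @export
upwelling_surface <- function(inv, factors = factor_set()) {
  inv <- as_inventory(inv)
  ov <- inv$overrides$upwelling_cm2
  if (!is.null(ov)) return(as.numeric(ov))
  frv <- inv$roughness_factor_vertical
  s <- inv$S_v_cm2 * frv
  if (nrow(inv$lateral_holes) > 0)
    s <- s - sum(inv$lateral_holes$area_cm2 * inv$lateral_holes$roughness)
  if (nrow(inv$inclined) > 0)
    s <- s + sum(inv$inclined$area_cm2 * frv *
                   inclined_upwelling_factor(inv$inclined$angle_deg,
                                             factors$inclined_model))
  max(0, s)
}

#' Nest-cavity opening area of a design
#'
#' Sum of the opening disc areas of all blind nest cavities. A
#' `nest_cavity_cm2` override takes precedence.
#'
#' @param inv A `reef_inventory` (or design).
#' @return Total cavity opening area in cm2.
#' @export
nest_cavity_surface <- function(inv) {
  inv <- as_inventory(inv)
  ov <- inv$overrides$nest_cavity_cm2
  if (!is.null(ov)) return(as.numeric(ov))
  sum(inv$nest_cavity_areas_cm2)
}

undefined_index <- function(dimension, why) {
  stop(sprintf("undefined %s index: %s", dimension, why), call. = FALSE)
}

#' Energy-modification partial index
#'
#' Ratio of the candidate's weighted sunlit-surface sum to the reference's.
#' Equals 1 when a design is compared against itself; values above 1 mean
#' more substrate-and-light capacity than the reference.
#'
#' @param candidate,reference `reef_inventory` objects (or designs).
#' @param factors A [factor_set()].
#' @return Dimensionless index (>= 0).
#' @export
energy_modification <- function(candidate, reference, factors = factor_set()) {
  den <- weighted_exposed_area(reference, factors)
  if (!is.finite(den) || den <= 0)
    undefined_index("energy", "reference contributes nothing to energy (zero weighted exposed area)")
  weighted_exposed_area(candidate, factors) / den
}

#' Nutrient-modification partial index
#'
#' Ratio of upwelling-generating surfaces. Lateral holes reduce the
#' numerator: they trade upwelling for interior circulation.
#'
#' @inheritParams energy_modification
#' @return Dimensionless index (>= 0).
#' @export
nutrient_modification <- function(candidate, reference, factors = factor_set()) {
  den <- upwelling_surface(reference, factors)
  if (!is.finite(den) || den <= 0)
    undefined_index("nutrient", "reference contributes nothing to upwelling (zero upwelling surface)")
  upwelling_surface(candidate, factors) / den
}

#' Habitat-modification partial index
#'
#' Ratio of total nest-cavity opening areas. The comparison requires a
#' reference that itself offers shelter: a reference without nest cavities
#' makes the index undefined.
#'
#' @inheritParams energy_modification
#' @return Dimensionless index (>= 0).
#' @export
habitat_modification <- function(candidate, reference) {
  den <- nest_cavity_surface(reference)
  if (!is.finite(den) || den <= 0)
    undefined_index("habitat", "reference has no nest cavities")
  nest_cavity_surface(candidate) / den
}

# round half-up (commercial rounding); base round() is round-half-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Comparative reef-design index
#'
#' Scores a candidate design against a reference of equal bounding volume as
#' the weighted sum of the three partial indices (energy, nutrient, habitat
#' modification). With unit weights a self-comparison scores 3; values above
#' 3 indicate a design with a higher overall positive impact on the
#' ecosystem than the reference.
#'
#' @param candidate,reference `ar_unit_design` or `reef_inventory` objects.
#' @param factors A [factor_set()]; its `weights` select and weight the
#'   dimensions. A zero weight skips that dimension entirely (including its
#'   preconditions), supporting nutrient-only or energy-plus-habitat runs.
#' @param rounding `"paper"` rounds each partial half-up to two decimals
#'   before summing (the display convention); `"full"` keeps full precision
#'   (preferred for programmatic comparison and ranking).
#' @param conventions Surface-accounting conventions forwarded to
#'   [compute_surface_inventory()] when designs are passed.
#' @param check_volume Warn when bounding volumes differ by more than 5%:
#'   the index compares impact per unit of occupied volume, so comparing
#'   very different sizes is misleading.
#' @return An `areit_report`: list with `EM`, `NM`, `HM`, `AREIT`, the
#'   intermediate surface sums for both designs, `weights` and `rounding`.
#' @export
areit_index <- function(candidate, reference, factors = factor_set(),
                        rounding = c("paper", "full"),
                        conventions = inventory_conventions(),
                        check_volume = TRUE) {
  rounding <- match.arg(rounding)
  cand <- as_inventory(candidate, conventions)
  ref <- as_inventory(reference, conventions)
  w <- factors$weights

  if (check_volume &&
      is.finite(cand$bounding_volume_m3) && is.finite(ref$bounding_volume_m3)) {
    rel <- abs(cand$bounding_volume_m3 - ref$bounding_volume_m3) /
      ref$bounding_volume_m3
    if (rel > 0.05)
      warning(sprintf(
        "bounding volumes differ by %.0f%%; the index compares designs of equal volume",
        100 * rel), call. = FALSE)
  }

  partial <- c(em = NA_real_, nm = NA_real_, hm = NA_real_)
  if (w["em"] > 0) partial["em"] <- energy_modification(cand, ref, factors)
  if (w["nm"] > 0) partial["nm"] <- nutrient_modification(cand, ref, factors)
  if (w["hm"] > 0) partial["hm"] <- habitat_modification(cand, ref)

  reported <- if (rounding == "paper") round_half_up(partial, 2) else partial
  active <- !is.na(reported)
  areit <- sum(w[active] * reported[active])

  structure(list(
    candidate = cand$design_name, reference = ref$design_name,
    EM = unname(reported["em"]), NM = unname(reported["nm"]),
    HM = unname(reported["hm"]),
    AREIT = areit,
    weights = w, rounding = rounding,
    detail = list(
      weighted_exposed_cm2 = weighted_exposed_area(cand, factors),
      weighted_exposed_ref_cm2 = weighted_exposed_area(ref, factors),
      upwelling_cm2 = upwelling_surface(cand, factors),
      upwelling_ref_cm2 = upwelling_surface(ref, factors),
      nest_cavity_cm2 = nest_cavity_surface(cand),
      nest_cavity_ref_cm2 = nest_cavity_surface(ref),
      partials_full = partial)
  ), class = "areit_report")
}

#' @export
print.areit_report <- function(x, ...) {
  cat(sprintf("<areit_report> %s vs reference %s (%s rounding)\n",
              x$candidate, x$reference, x$rounding))
  fmt <- function(v) if (is.na(v)) "  (skipped)" else sprintf("%8.2f", v)
  cat(sprintf("  EM %s   NM %s   HM %s\n", fmt(x$EM), fmt(x$NM), fmt(x$HM)))
  cat(sprintf("  AREIT = %.2f (weights %s)\n", x$AREIT,
              paste(sprintf("%s=%g", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Export an index report
#'
#' @param report An `areit_report`.
#' @param path Destination file; `.json` or `.csv` by extension.
#' @return `path`, invisibly.
#' @export
write_index_report <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(candidate = report$candidate,
                     reference = report$reference,
                     EM = report$EM, NM = report$NM, HM = report$HM,
                     AREIT = report$AREIT, rounding = report$rounding)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
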