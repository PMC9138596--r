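GRAVITY <- 9.81  # m/s2

#' Design sea state at the reef site
#'
#' @param hs Significant wave height in metres.
#' @param tp Peak period in seconds.
#' @param depth Water depth at the site in metres.
#' @param n_waves Number of waves in the design sea state (default 1000,
#'   roughly a 3-hour storm); drives the Rayleigh maximum-wave statistic.
#' @param current Depth-averaged steady current speed in m/s (default 0),
#'   superposed on the orbital velocity in the force analysis.
#' @param rho Water density in kg/m3 (default seawater).
#' @return A `wave_conditions` list.
#' @export
wave_conditions <- function(hs, tp, depth, n_waves = 1000, current = 0,
                            rho = 1025) {
  stopifnot(hs >= 0, tp > 0, depth > 0, n_waves >= 1)
  structure(list(hs = hs, tp = tp, depth = depth, n_waves = n_waves,
                 current = current, rho = rho),
            class = "wave_conditions")
}

#' Solve the linear dispersion relation
#'
#' Finds the wavelength L such that `omega^2 = g k tanh(k h)` with
#' `k = 2 pi / L`, by Newton iteration from the deep-water wavenumber.
#' Converges to a relative residual below 1e-12 across the full range of
#' engineering interest (periods of a few seconds to swell, depths from
#' surf zone to open ocean).
#'
#' @param period Wave period in seconds.
#' @param depth Water depth in metres.
#' @param g Gravitational acceleration, m/s2.
#' @return Wavelength in metres.
#' @export
solve_dispersion <- function(period, depth, g = GRAVITY) {
  stopifnot(period > 0, depth > 0)
  omega <- 2 * pi / period
  # initial guess: deep-water wavenumber corrected by tanh (Eckart-type)
  k0 <- omega^2 / g
  k <- k0 / sqrt(tanh(k0 * depth))
  for (i in 1:100) {
    th <- tanh(k * depth)
    f <- g * k * th - omega^2
    fp <- g * th + g * k * depth * (1 - th^2)
    step <- f / fp
    k <- k - step
    if (abs(f) < 1e-13 * omega^2 && abs(step) < 1e-14 * k) break
  }
  2 * pi / k
}

#' Estimate the design wave from a sea state
#'
#' The extreme individual wave used for force analysis. Its height is the
#' Rayleigh-distribution most probable maximum of the sea state,
#' `Hs * sqrt(ln(N) / 2)`, capped by the depth-limited breaking criterion
#' `gamma * h`. The governing wave theory is selected by the Ursell number
#' `H L^2 / h^3`: above the threshold the wave is strongly nonlinear and
#' cnoidal theory applies, otherwise linear (Airy) theory.
#'
#' @param conditions A [wave_conditions()].
#' @param gamma Breaker index (default 0.78).
#' @param ursell_threshold Ursell number above which cnoidal theory is
#'   selected (default 26).
#' @param g Gravitational acceleration, m/s2.
#' @return A `design_wave` list: `height`, `period`, `wavelength`,
#'   `wavenumber`, `theory`, `ursell`, `breaking_limited`.
#' @export
design_wave <- function(conditions, gamma = 0.78, ursell_threshold = 26,
                        g = GRAVITY) {
  h <- conditions$depth
  h_rayleigh <- conditions$hs * sqrt(log(conditions$n_waves) / 2)
  h_break <- gamma * h
  hmax <- min(h_rayleigh, h_break)
  L <- solve_dispersion(conditions$tp, h, g)
  ur <- if (hmax > 0) hmax * L^2 / h^3 else 0
  structure(list(
    height = hmax,
    period = conditions$tp,
    wavelength = L,
    wavenumber = 2 * pi / L,
    theory = if (ur > ursell_threshold) "cnoidal" else "linear",
    ursell = ur,
    breaking_limited = h_rayleigh > h_break
  ), class = "design_wave")
}

# cosh(k z) / sinh(k h), stable for large k h
cosh_over_sinh <- function(k, z, h) {
  (exp(k * (z - h)) + exp(-k * (z + h))) / (1 - exp(-2 * k * h))
}

#' Linear (Airy) wave kinematics
#'
#' Horizontal orbital velocity and acceleration at elevation `z` above the
#' bed, with a steady current superposed on the velocity. Phase 0 is the
#' crest: velocity is maximal there and acceleration zero (they are in
#' quadrature).
#'
#' @param wave A `design_wave` (fields `height`, `period`, `wavenumber`).
#' @param depth Water depth in metres.
#' @param z Elevation above the bed in metres, within `[0, depth]`.
#' @param current Steady current speed, m/s.
#' @param phase Wave phase in radians (vectorised).
#' @return List with `u` (m/s) and `a` (m/s2), same length as `phase`.
#' @export
linear_kinematics <- function(wave, depth, z, current = 0, phase = 0) {
  if (any(z < 0) || any(z > depth))
    stop("elevation z must lie inside the water column [0, depth]",
         call. = FALSE)
  if (wave$height <= 0)
    return(list(u = rep(current, length(phase)),
                a = rep(0, length(phase))))
  omega <- 2 * pi / wave$period
  k <- wave$wavenumber
  amp <- wave$height / 2 * omega * cosh_over_sinh(k, z, depth)
  list(u = current + amp * cos(phase),
       a = amp * omega * sin(phase))
}

# First-order cnoidal wave parameters: solve the elliptic parameter m from
# (H, T, h) via the Ursell relation Ur = 16 m K(m)^2 / 3 coupled with the
# celerity c^2 = g h [1 + (H/(m h)) (2 - m - 3 E/K)], iterating L = c T.
cnoidal_solve <- function(H, T, h, g = GRAVITY, tol = 1e-12, max_iter = 200) {
  stopifnot(H > 0, T > 0, h > 0)
  m_from_ursell <- function(ur) {
    target <- 3 * ur / 16  # = m K(m)^2, increasing from 0 to Inf
    f <- function(m) m * pracma::ellipke(m)$k^2 - target
    stats::uniroot(f, lower = 1e-15, upper = 1 - 1e-15, tol = 1e-15)$root
  }
  L <- sqrt(g * h) * T  # shallow-water first guess
  m <- NA_real_
  for (i in seq_len(max_iter)) {
    ur <- H * L^2 / h^3
    m <- m_from_ursell(ur)
    ek <- pracma::ellipke(m)
    c2 <- g * h * (1 + (H / (m * h)) * (2 - m - 3 * ek$e / ek$k))
    if (!is.finite(c2) || c2 <= 0)
      stop(sprintf(
        "cnoidal parameter solve failed: celerity undefined at Ursell %.3g (m = %.3g); wave outside the cnoidal validity range",
        ur, m), call. = FALSE)
    L_new <- sqrt(c2) * T
    if (abs(L_new - L) < tol * L) { L <- L_new; break }
    L <- L_new
  }
  ek <- pracma::ellipke(m)
  list(m = m, K = ek$k, E = ek$e, L = L, c = L / T,
       eta_trough = (H / m) * (1 - m - ek$e / ek$k),
       ursell = H * L^2 / h^3)
}

#' First-order cnoidal wave kinematics
#'
#' Surface elevation and horizontal velocity of a nonlinear shallow-water
#' wave with a cn-squared (Jacobi elliptic) profile. The elliptic parameter
#' m is solved from height, period and depth; as m tends to 0 the profile
#' becomes sinusoidal, as m tends to 1 it becomes the solitary wave. The
#' first-order velocity is depth-uniform, `u = c eta / h`; phase 0 is the
#' crest and one period spans `2 pi` radians of phase.
#'
#' @param wave A `design_wave`.
#' @param depth Water depth in metres.
#' @param z Elevation above the bed (retained for interface symmetry with
#'   [linear_kinematics()]; the first-order velocity does not vary over the
#'   column).
#' @param current Steady current, m/s.
#' @param phase Phase in radians (vectorised).
#' @param m Optional: impose the elliptic parameter directly instead of
#'   solving it from `(H, T, h)` (used for limit studies).
#' @return List with `u`, `a`, `eta` (surface elevation about still water,
#'   m), and the solved parameters `m`, `wavelength`, `celerity`.
#' @export
cnoidal_kinematics <- function(wave, depth, z = depth / 2, current = 0,
                               phase = 0, m = NULL) {
  if (any(z < 0) || any(z > depth))
    stop("elevation z must lie inside the water column [0, depth]",
         call. = FALSE)
  H <- wave$height
  if (H <= 0)
    return(list(u = rep(current, length(phase)), a = rep(0, length(phase)),
                eta = rep(0, length(phase)), m = 0,
                wavelength = wave$wavelength, celerity = NA_real_))
  if (is.null(m)) {
    sol <- cnoidal_solve(H, wave$period, depth)
  } else {
    stopifnot(m > 0, m < 1)
    ek <- pracma::ellipke(m)
    c2 <- GRAVITY * depth *
      (1 + (H / (m * depth)) * (2 - m - 3 * ek$e / ek$k))
    if (!is.finite(c2) || c2 <= 0)
      stop("imposed elliptic parameter incompatible with H/h: celerity undefined",
           call. = FALSE)
    sol <- list(m = m, K = ek$k, E = ek$e, L = sqrt(c2) * wave$period,
                c = sqrt(c2), eta_trough = (H / m) * (1 - m - ek$e / ek$k))
  }
  arg <- sol$K * phase / pi          # one wave period <-> 2K in cn argument
  sj <- pracma::ellipj(arg, sol$m)
  eta <- sol$eta_trough + H * sj$cn^2
  u <- current + sol$c * eta / depth
  # du/dt with phase advancing at 2*pi/T: d(cn^2)/d(arg) = -2 cn sn dn
  a <- -sol$c / depth * H * 2 * sj$cn * sj$sn * sj$dn *
    sol$K / pi * 2 * pi / wave$period
  list(u = u, a = a, eta = eta, m = sol$m, wavelength = sol$L,
       celerity = sol$c)
}

#' Morison force on a submerged bluff body
#'
#' Drag plus inertia: `F = 0.5 rho Cd A u |u| + rho Cm V a`. The drag term
#' is quadratic and odd in the velocity; the inertia term linear in the
#' acceleration.
#'
#' @param u Horizontal velocity, m/s (vectorised).
#' @param a Horizontal acceleration, m/s2.
#' @param area Projected frontal area, m2.
#' @param volume Displaced volume, m3.
#' @param rho Water density, kg/m3.
#' @param cd,cm Drag and inertia coefficients.
#' @return Force in newtons, same length as `u`.
#' @export
morison_force <- function(u, a, area, volume, rho = 1025, cd = 1.05,
                          cm = 2.0) {
  stopifnot(area >= 0, volume >= 0)
  0.5 * rho * cd * area * u * abs(u) + rho * cm * volume * a
}

#' Force and stability coefficients
#'
#' All empirical coefficients of the force analysis in one place. Defaults
#' suit a cubic concrete block on sand; every value is site- and
#' design-specific and should be reviewed.
#'
#' @param cd Drag coefficient (default 1.05, cube face-on).
#' @param cm Inertia coefficient (default 2.0).
#' @param cl Lift coefficient (default 0: no lift unless supplied).
#' @param friction Concrete-on-seabed friction coefficient (default 0.6).
#' @param n_strips Number of vertical strips for force integration over the
#'   unit height (1 = evaluate at mid-height; use 10+ for tall units).
#' @param slab_plan_area Ballast-slab plan area in m2; `NULL` means the
#'   unit footprint.
#' @param slab_density Slab concrete density, kg/m3.
#' @param g Gravitational acceleration, m/s2.
#' @return A `stability_coefficients` list.
#' @export
stability_coefficients <- function(cd = 1.05, cm = 2.0, cl = 0,
                                   friction = 0.6, n_strips = 1,
                                   slab_plan_area = NULL,
                                   slab_density = 2400, g = GRAVITY) {
  stopifnot(cd >= 0, cm >= 0, cl >= 0, friction > 0, n_strips >= 1)
  structure(list(cd = cd, cm = cm, cl = cl, friction = friction,
                 n_strips = as.integer(n_strips),
                 slab_plan_area = slab_plan_area,
                 slab_density = slab_density, g = g),
            class = "stability_coefficients")
}

unit_masses <- function(design, coefficients) {
  v_prism <- design$length * design$width * design$height
  m_prism <- if (is.finite(design$mass_t)) design$mass_t * 1000
             else design$bulk_density * v_prism
  plan <- coefficients$slab_plan_area %||% (design$length * design$width)
  v_slab <- plan * design$slab_height
  m_slab <- coefficients$slab_density * v_slab
  list(v_prism = v_prism, m_prism = m_prism, v_slab = v_slab,
       m_slab = m_slab, slab_plan = plan)
}

kinematics_at <- function(wave, depth, z, current, phase) {
  if (wave$theory == "cnoidal") {
    k <- cnoidal_kinematics(wave, depth, z, current, phase)
    list(u = k$u, a = k$a)
  } else {
    linear_kinematics(wave, depth, z, current, phase)
  }
}

#' Sliding and overturning check of a reef unit under the design wave
#'
#' Evaluates the Morison force over a full wave cycle at the phase of
#' maximum loading, then forms the sliding safety factor
#' `mu (W_sub - F_lift) / F_h` and the overturning safety factor (restoring
#' over overturning moment about the downstream bottom edge). The ballast
#' slab contributes weight, frontal area and moment arms. With no wave and
#' no current the report is flagged as a no-load case and both factors are
#' infinite.
#'
#' @param design An `ar_unit_design` (its `slab_height` is the slab used).
#' @param wave A `design_wave`.
#' @param conditions The [wave_conditions()] (depth, current, density).
#' @param coefficients A [stability_coefficients()].
#' @param n_phase Number of phases swept over one cycle.
#' @return A `stability_report`: forces (N), submerged weight (N), safety
#'   factors, the phase of maximum load, and a `no_load` flag.
#' @export
stability_check <- function(design, wave, conditions,
                            coefficients = stability_coefficients(),
                            n_phase = 721) {
  stop_if_invalid(design)
  h <- conditions$depth
  geo <- unit_masses(design, coefficients)
  slab_w <- if (geo$v_slab > 0) sqrt(geo$slab_plan *
                                       design$width / design$length)
            else design$width
  total_h <- design$slab_height + design$height
  if (total_h > h)
    warning("unit is taller than the water depth; kinematics clamped to the column",
            call. = FALSE)

  rho <- conditions$rho
  g <- coefficients$g
  w_sub <- (geo$m_prism + geo$m_slab) * g - rho * g * (geo$v_prism + geo$v_slab)

  phases <- seq(0, 2 * pi, length.out = n_phase)
  # strips over the prism height (the slab is squat; its drag area is added
  # to the lowest strip)
  ns <- coefficients$n_strips
  strip_h <- design$height / ns
  strip_z <- design$slab_height + (seq_len(ns) - 0.5) * strip_h
  strip_z <- pmin(strip_z, h)
  strip_area <- rep(design$width * strip_h, ns)
  strip_area[1] <- strip_area[1] + slab_w * design$slab_height
  strip_vol <- rep(geo$v_prism / ns, ns)
  strip_vol[1] <- strip_vol[1] + geo$v_slab

  f_h <- rep(0, n_phase)
  moment <- rep(0, n_phase)
  u_mid <- rep(conditions$current, n_phase)
  for (s in seq_len(ns)) {
    kin <- kinematics_at(wave, h, strip_z[s], conditions$current, phases)
    fs <- morison_force(kin$u, kin$a, strip_area[s], strip_vol[s],
                        rho, coefficients$cd, coefficients$cm)
    f_h <- f_h + fs
    moment <- moment + fs * strip_z[s]
    if (s == ceiling(ns / 2)) u_mid <- kin$u
  }

  i_max <- which.max(abs(f_h))
  f_star <- f_h[i_max]
  f_lift <- 0.5 * rho * coefficients$cl * geo$slab_plan * u_mid[i_max]^2

  no_load <- wave$height <= 0 && conditions$current == 0
  base_len <- if (geo$v_slab > 0) max(design$length,
                                      geo$slab_plan / slab_w)
              else design$length
  if (no_load || abs(f_star) < 1e-9) {
    sf_slide <- Inf
    sf_turn <- Inf
  } else {
    sf_slide <- coefficients$friction * (w_sub - f_lift) / abs(f_star)
    m_restoring <- (w_sub - f_lift) * base_len / 2
    m_overturn <- abs(moment[i_max])
    sf_turn <- m_restoring / m_overturn
  }

  # phase-resolved component maxima for reporting
  kin0 <- kinematics_at(wave, h, pmin(design$slab_height + design$height / 2, h),
                        conditions$current, phases)
  drag_max <- max(abs(0.5 * rho * coefficients$cd * sum(strip_area) *
                        kin0$u * abs(kin0$u)))
  inertia_max <- max(abs(rho * coefficients$cm * sum(strip_vol) * kin0$a))

  structure(list(
    design = design$name,
    theory = wave$theory,
    horizontal_force_N = abs(f_star),
    drag_max_N = drag_max,
    inertia_max_N = inertia_max,
    lift_force_N = f_lift,
    submerged_weight_N = w_sub,
    sliding_sf = sf_slide,
    overturning_sf = sf_turn,
    phase_max = phases[i_max],
    slab_height_m = design$slab_height,
    no_load = no_load
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s (%s theory)\n", x$design, x$theory))
  if (x$no_load) {
    cat("  no load case: zero wave and current\n")
    return(invisible(x))
  }
  cat(sprintf("  F_h = %.0f N (drag max %.0f, inertia max %.0f), lift %.0f N\n",
              x$horizontal_force_N, x$drag_max_N, x$inertia_max_N,
              x$lift_force_N))
  cat(sprintf("  W_sub = %.0f N | sliding SF %.2f, overturning SF %.2f (slab %.2f m)\n",
              x$submerged_weight_N, x$sliding_sf, x$overturning_sf,
              x$slab_height_m))
  invisible(x)
}

#' Size the ballast slab for stability
#'
#' Smallest slab height (to the given resolution) at which both the sliding
#' and the overturning safety factor meet their targets under the design
#' wave; 0 when the bare unit already passes.
#'
#' @param design An `ar_unit_design` (its own `slab_height` is ignored; the
#'   slab is what is being sized).
#' @param wave A `design_wave`.
#' @param conditions The [wave_conditions()].
#' @param coefficients A [stability_coefficients()].
#' @param targets Named targets `c(sliding =, overturning =)`.
#' @param resolution Slab-height step in metres.
#' @param max_height Largest slab height tried, metres.
#' @return Required slab height in metres.
#' @export
size_slab <- function(design, wave, conditions,
                      coefficients = stability_coefficients(),
                      targets = c(sliding = 1.2, overturning = 1.2),
                      resolution = 0.05, max_height = 5) {
  stopifnot(all(targets > 0), resolution > 0)
  heights <- seq(0, max_height, by = resolution)
  last <- NULL
  for (hgt in heights) {
    d <- design
    d$slab_height <- hgt
    rep <- stability_check(d, wave, conditions, coefficients)
    last <- rep
    if (rep$sliding_sf >= targets["sliding"] &&
        rep$overturning_sf >= targets["overturning"])
      return(hgt)
  }
  limiting <- if (last$sliding_sf < targets["sliding"]) "sliding"
              else "overturning"
  stop(sprintf(
    "no slab height up to %.2f m meets the targets; limiting mode: %s (SF %.2f < %.2f)",
    max_height, limiting,
    if (limiting == "sliding") last$sliding_sf else last$overturning_sf,
    targets[limiting]), call. = FALSE)
}
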