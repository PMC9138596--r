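test_that("dispersion solver matches limits and an independent bisection oracle", {
  # deep water: L -> g T^2 / (2 pi)
  expect_equal(solve_dispersion(16.1, 4000), 9.81 * 16.1^2 / (2 * pi),
               tolerance = 1e-9)
  # shallow water: phase speed -> sqrt(g h)
  for (h in c(0.5, 1, 2)) {
    L <- solve_dispersion(25, h)
    expect_equal(L / 25, sqrt(9.81 * h), tolerance = 5e-3)
  }
  expect_equal(solve_dispersion(8, 10), oracle_dispersion(8, 10),
               tolerance = 1e-9)
  expect_equal(round(solve_dispersion(8, 10), 1), 70.9)
})

test_that("dispersion residual stays below tolerance across the parameter grid", {
  for (T in c(2, 5, 10, 16.1, 25)) {
    for (h in c(1, 5, 20, 80, 200)) {
      L <- solve_dispersion(T, h)
      k <- 2 * pi / L
      omega <- 2 * pi / T
      expect_lt(abs(9.81 * k * tanh(k * h) - omega^2) / omega^2, 1e-10)
    }
  }
})

test_that("design wave applies the Rayleigh statistic and the breaking cap", {
  deep <- wave_conditions(hs = 5.5, tp = 16.1, depth = 500, n_waves = 1000)
  dw <- design_wave(deep)
  expect_equal(dw$height, 5.5 * sqrt(log(1000) / 2), tolerance = 1e-12)
  expect_equal(round(dw$height, 1), 10.2)
  expect_false(dw$breaking_limited)
  expect_equal(dw$theory, "linear")  # deep water: tiny Ursell number

  calm <- design_wave(wave_conditions(hs = 0, tp = 10, depth = 10))
  expect_equal(calm$height, 0)

  shallow <- design_wave(wave_conditions(hs = 20, tp = 12, depth = 5),
                         gamma = 0.78)
  expect_equal(shallow$height, 3.9)
  expect_true(shallow$breaking_limited)
  expect_equal(shallow$theory, "cnoidal")  # depth-limited wave: huge Ursell
})

test_that("linear kinematics match the Airy expressions and degenerate cleanly", {
  wc <- wave_conditions(hs = 2, tp = 10, depth = 8)
  wave <- list(height = 2, period = 10,
               wavelength = solve_dispersion(10, 8),
               wavenumber = 2 * pi / solve_dispersion(10, 8),
               theory = "linear")
  k <- wave$wavenumber
  phases <- seq(0, 2 * pi, length.out = 9)
  kin <- linear_kinematics(wave, 8, 1, 0, phases)
  # independent textbook evaluation: u = (pi H / T) cosh(kz)/sinh(kh) cos(phase)
  amp <- pi * 2 / 10 * cosh(k * 1) / sinh(k * 8)
  expect_equal(kin$u, amp * cos(phases), tolerance = 1e-12)
  expect_equal(kin$a, amp * 2 * pi / 10 * sin(phases), tolerance = 1e-12)
  # crest: maximal velocity, zero acceleration (quadrature)
  expect_equal(which.max(kin$u), 1)
  expect_equal(kin$a[1], 0)

  still <- linear_kinematics(list(height = 0, period = 10, wavenumber = k),
                             8, 1, current = 0.3, phases)
  expect_equal(still$u, rep(0.3, 9))
  expect_equal(still$a, rep(0, 9))

  expect_error(linear_kinematics(wave, 8, 9, 0, 0), "water column")
})

test_that("cnoidal kinematics reduce to linear theory at small Ursell number", {
  h <- 4; T <- 30; H <- 2.4e-5
  L <- solve_dispersion(T, h)
  wave <- list(height = H, period = T, wavelength = L,
               wavenumber = 2 * pi / L, theory = "cnoidal")
  phases <- seq(0, 2 * pi, length.out = 73)
  cn <- cnoidal_kinematics(wave, h, h / 2, 0, phases)
  expect_lt(cn$m, 0.01)
  lin <- linear_kinematics(wave, h, h / 2, 0, phases)
  scale <- max(abs(lin$u))
  expect_lt(max(abs(cn$u - lin$u)) / scale, 0.01)
})

test_that("cnoidal kinematics approach the solitary-wave profile at m -> 1", {
  h <- 5; T <- 30; H <- 2
  wave <- list(height = H, period = T, theory = "cnoidal")
  phases <- seq(-pi, pi, length.out = 101)
  cn <- cnoidal_kinematics(wave, h, h / 2, 0, phases)
  expect_gt(cn$m, 0.999)
  # trough flattens towards still water and the crest matches the
  # closed-form sech^2 solitary profile
  trough <- min(cn$eta)
  expect_lt(abs(trough) / H, 0.1)
  K <- pracma::ellipke(cn$m)$k
  sech2 <- H / cosh(K * phases / pi)^2  # closed-form solitary profile
  expect_equal(cn$eta - trough, sech2, tolerance = 0.01)
})

test_that("cnoidal crests are faster than troughs and the profile is continuous", {
  h <- 6; T <- 14; H <- 2.5
  wave <- list(height = H, period = T, theory = "cnoidal")
  phases <- seq(0, 2 * pi, length.out = 1441)
  cn <- cnoidal_kinematics(wave, h, h / 2, 0, phases)
  expect_gt(cn$m, 0)
  expect_gt(max(cn$u), abs(min(cn$u)))
  expect_lt(max(abs(diff(cn$u))), 0.05 * diff(range(cn$u)))
  # one wave of mass flux balance: mean elevation near zero (first order)
  expect_lt(abs(mean(cn$eta[-1])) / H, 0.05)
})

test_that("Morison force obeys its quadratic-drag and linear-inertia structure", {
  expect_equal(morison_force(0, 0, 2, 1), 0)
  expect_equal(morison_force(2, 0, 2.25, 0, rho = 1025, cd = 1.05, cm = 0),
               4843.125)
  # drag quadratic and odd in u
  u <- seq(-3, 3, by = 0.5)
  f <- morison_force(u, 0, 1.5, 0)
  expect_equal(f, -rev(f))
  expect_equal(morison_force(2 * u, 0, 1.5, 0), 4 * f)
  # inertia linear in a
  a <- seq(-2, 2, by = 0.5)
  g1 <- morison_force(0, a, 0, 2.5)
  expect_equal(morison_force(0, 3 * a, 0, 2.5), 3 * g1)
  expect_equal(g1, 1025 * 2.0 * 2.5 * a)
})

test_that("stability report: no-load flagging and safety-factor composition", {
  gal <- galician_unit()
  calm <- wave_conditions(hs = 0, tp = 10, depth = 10)
  rep0 <- stability_check(gal, design_wave(calm), calm)
  expect_true(rep0$no_load)
  expect_equal(rep0$sliding_sf, Inf)
  expect_equal(rep0$overturning_sf, Inf)

  wc <- wave_conditions(hs = 1.2, tp = 9, depth = 10, current = 0.08)
  dw <- design_wave(wc)
  rep <- stability_check(gal, dw, wc)
  expect_gt(rep$horizontal_force_N, 0)
  expect_gt(rep$submerged_weight_N, 0)
  expect_equal(rep$sliding_sf,
               0.6 * (rep$submerged_weight_N - rep$lift_force_N) /
                 rep$horizontal_force_N,
               tolerance = 1e-10)
})

test_that("safety factors fall monotonically as the design wave grows", {
  gal <- galician_unit()
  sf_slide <- sf_turn <- numeric()
  for (hs in c(0.5, 1.0, 1.5, 2.0)) {
    wc <- wave_conditions(hs = hs, tp = 9, depth = 10)
    rep <- stability_check(gal, design_wave(wc), wc)
    sf_slide <- c(sf_slide, rep$sliding_sf)
    sf_turn <- c(sf_turn, rep$overturning_sf)
  }
  expect_true(all(diff(sf_slide) < 0))
  expect_true(all(diff(sf_turn) < 0))
})

test_that("slab sizing inverts the stability check", {
  gal <- galician_unit()
  wc <- wave_conditions(hs = 1.2, tp = 9, depth = 10)
  dw <- design_wave(wc)
  targets <- c(sliding = 1.2, overturning = 1.2)

  # already stable bare: H = 0
  expect_equal(size_slab(gal, dw, wc, targets = targets), 0)

  # heavier sea: returned H passes, H - resolution fails
  wc2 <- wave_conditions(hs = 1.6, tp = 10, depth = 9)
  dw2 <- design_wave(wc2)
  res <- 0.05
  H <- size_slab(gal, dw2, wc2, targets = targets, resolution = res)
  expect_gt(H, 0)
  with_slab <- gal; with_slab$slab_height <- H
  rep <- stability_check(with_slab, dw2, wc2)
  expect_true(rep$sliding_sf >= targets["sliding"] &&
                rep$overturning_sf >= targets["overturning"])
  slim <- gal; slim$slab_height <- H - res
  rep2 <- stability_check(slim, dw2, wc2)
  expect_true(rep2$sliding_sf < targets["sliding"] ||
                rep2$overturning_sf < targets["overturning"])

  # required height never grows with unit mass
  masses <- c(5, 6, 8, 12)
  req <- vapply(masses, function(m) {
    d <- gal; d$mass_t <- m
    size_slab(d, dw2, wc2, targets = targets, resolution = res)
  }, numeric(1))
  expect_true(all(diff(req) <= 0))

  # relaxing the targets never increases the requirement
  H_relaxed <- size_slab(gal, dw2, wc2,
                         targets = targets / 2, resolution = res)
  expect_lte(H_relaxed, H)

  # infeasible case names the limiting mode
  storm <- wave_conditions(hs = 6, tp = 14, depth = 12)
  expect_error(size_slab(gal, design_wave(storm), storm, targets = targets,
                         max_height = 0.5),
               "limiting mode")
})
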