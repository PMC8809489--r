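test_that("enthalpy carries the Avogadro PV conversion", {
  expect_equal(enthalpy(0, -100, 300), -100)
  expect_equal(enthalpy(10, -100, 300), -100 + 1806.642228, tolerance = 1e-6)
  # PV term is linear in V
  expect_equal(enthalpy(10, 0, 600), 2 * enthalpy(10, 0, 300))
  expect_error(enthalpy(1, -100, -5), class = "polyscape_value_error")
})

test_that("pv_series validates and sorts its points", {
  s <- pv_series("x", c(5, 0, 10), c(-99, -100, -98), c(290, 300, 280))
  expect_equal(s$pressure, c(0, 5, 10))
  expect_equal(s$enthalpy[1], -100)
  expect_error(pv_series("x", c(0, 0), c(1, 2), c(10, 10)),
               class = "polyscape_value_error")
  expect_warning(pv_series("x", c(0, 1), c(-1, -1), c(100, 101)),
                 "increase with pressure")
})

test_that("relative enthalpy curves match the constant-offset closed form", {
  p <- seq(0, 15, by = 0.1)
  ref <- pv_series("Y", p, rep(-100, length(p)), 300 - 2 * p)
  s15 <- pv_series("s15", p, rep(-96.4, length(p)), 298.8 - 2 * p)
  # dE = 3.6, dV = -1.2 constant: dH(P) = 3.6 - 0.722657 P
  dc <- relative_enthalpy_curve(s15, ref, p)
  expect_equal(dc$delta_h, 3.6 - 1.2 * 0.602214076 * p, tolerance = 1e-3)
  # a series against itself is identically zero
  self <- relative_enthalpy_curve(ref, ref, p)
  expect_equal(self$delta_h, rep(0, length(p)))
  # dH(0) equals the zero-pressure relative lattice energy
  expect_equal(dc$delta_h[1], 3.6)
  # extrapolation beyond 5% of the sampled range is refused
  expect_error(relative_enthalpy_curve(s15, ref, seq(0, 16, by = 0.5)),
               class = "polyscape_coverage_error")
})

test_that("crossover detection locates the closed-form root", {
  p <- seq(0, 15, by = 0.1)
  ref <- pv_series("Y", p, rep(-100, length(p)), 300 - 2 * p)
  s15 <- pv_series("s15", p, rep(-96.4, length(p)), 298.8 - 2 * p)
  r <- crossover_pressure(relative_enthalpy_curve(s15, ref, p))
  expect_length(r, 1)
  expect_equal(r, 3.6 / (1.2 * 0.602214076), tolerance = 1e-3 / 4.98)
  expect_equal(round(r, 4), 4.9816, tolerance = 2e-4)

  # strictly positive curve: no crossing
  up <- pv_series("up", p, rep(-90, length(p)), 300 - 2 * p)
  expect_length(crossover_pressure(relative_enthalpy_curve(up, ref, p)), 0)

  # cubic with two roots in range, against polyroot
  coef <- c(-2, 3.2, -0.9, 0.06)
  dh <- coef[1] + coef[2] * p + coef[3] * p^2 + coef[4] * p^3
  roots <- sort(Re(polyroot(coef)[abs(Im(polyroot(coef))) < 1e-9]))
  roots <- roots[roots >= 0 & roots <= 15]
  found <- crossover_pressure(data.frame(pressure = p, delta_h = dh))
  expect_length(found, length(roots))
  expect_equal(found, roots, tolerance = 1e-3)

  # grid refinement x2 changes crossovers by < 1e-3 GPa
  p2 <- seq(0, 15, by = 0.05)
  ref2 <- pv_series("Y", p2, rep(-100, length(p2)), 300 - 2 * p2)
  s152 <- pv_series("s15", p2, rep(-96.4, length(p2)), 298.8 - 2 * p2)
  r2 <- crossover_pressure(relative_enthalpy_curve(s152, ref2, p2))
  expect_equal(r, r2, tolerance = 1e-3)
})

test_that("the Birch-Murnaghan fit recovers known parameters", {
  v <- seq(280, 360, by = 5)
  e <- birch_murnaghan_energy(v, -100, 320, 12, 6)
  fit <- fit_eos(v, e)
  expect_equal(fit$e0, -100, tolerance = 1e-6)
  expect_equal(fit$v0, 320, tolerance = 1e-6 * 320)
  expect_equal(fit$b0, 12, tolerance = 1e-6 * 12)
  expect_equal(fit$b0p, 6, tolerance = 1e-5 * 6)
  expect_lt(attr(fit, "rms_residual"), 1e-8)

  expect_error(fit_eos(v[1:3], e[1:3]), class = "polyscape_value_error")
  expect_error(fit_eos(seq(318, 322, 1), birch_murnaghan_energy(seq(318, 322, 1), -100, 320, 12, 6)),
               class = "polyscape_value_error")
})

test_that("fitted B0 matches the quadratic-well curvature near V0", {
  v0 <- 320; b0 <- 12
  v <- seq(0.93 * v0, 1.07 * v0, length.out = 15)
  # harmonic well with curvature B0 / V0 (0.602214076 converts GPa to kJ/mol/A^3)
  e <- -100 + 0.5 * (b0 * 0.602214076 / v0) * (v - v0)^2
  fit <- fit_eos(v, e)
  expect_equal(fit$b0, b0, tolerance = 0.05 * b0)
})

test_that("EOS sampling and analytic crossovers are self-consistent", {
  ea <- eos_params(-100, 320, 12, 6)
  eb <- eos_params(-96.4, 318.8, 12, 6)
  grid <- seq(0, 15, by = 0.1)
  gp <- generate_pv_series(ea, eb, grid)
  expect_length(gp$crossovers, 1)
  num <- crossover_pressure(relative_enthalpy_curve(gp$series_b, gp$series_a,
                                                    grid))
  expect_equal(num, gp$crossovers, tolerance = 1e-3)

  # identical phases: dH = 0 everywhere, no crossover
  same <- generate_pv_series(ea, ea, grid)
  expect_length(same$crossovers, 0)
  dc <- relative_enthalpy_curve(same$series_b, same$series_a, grid)
  expect_equal(max(abs(dc$delta_h)), 0)

  # reversed pair: same crossover, sign-flipped curve
  rev <- generate_pv_series(eb, ea, grid)
  expect_equal(rev$crossovers, gp$crossovers, tolerance = 1e-9)
})

test_that("pressure screening reports orderings and crossovers", {
  p <- seq(0, 15, by = 0.1)
  y <- pv_series("Y", p, rep(-100, length(p)), 300 - 2 * p)
  s15 <- pv_series("s15", p, rep(-96.4, length(p)), 298.8 - 2 * p)
  scr <- pressure_screen(list(Y = y, s15 = s15), "Y", p)
  expect_equal(scr$most_stable[1], "Y")
  expect_equal(scr$most_stable[length(p)], "s15")
  expect_equal(nrow(scr$crossovers), 1)
  expect_equal(scr$crossovers$pressure, 4.9816, tolerance = 1e-3)

  # identical series: reference never displaced, no crossovers
  y2 <- pv_series("Y2", p, rep(-100, length(p)), 300 - 2 * p)
  scr2 <- pressure_screen(list(Y = y, Y2 = y2), "Y", p)
  expect_equal(nrow(scr2$crossovers), 0)

  # ordering at fixed P is invariant to a constant energy shift
  y3 <- pv_series("Y", p, rep(-100, length(p)) + 5, 300 - 2 * p)
  s153 <- pv_series("s15", p, rep(-96.4, length(p)) + 5, 298.8 - 2 * p)
  scr3 <- pressure_screen(list(Y = y3, s15 = s153), "Y", p)
  expect_equal(scr3$most_stable, scr$most_stable)
})
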