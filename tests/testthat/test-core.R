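test_that("spec constructors enforce their physical invariants", {
  expect_error(fluid_spec(-1, 1e-2), class = "cidep_invalid_input")
  expect_error(particle_spec(0, 2.55, 1e-3), class = "cidep_invalid_input")
  # inner radius must stay positive: Rc > W/2
  expect_error(channel_spec(width = 2e-4, mean_radius = 0.9e-4),
               class = "cidep_invalid_input")
  ch <- channel_spec(width = 2e-4, mean_radius = 1e-3)
  expect_equal(ch$outer_radius - ch$inner_radius, ch$width)
  expect_error(drive_spec(100, ac_ratio = -1), class = "cidep_invalid_input")
  expect_error(dimensionless_design(1, 0.4, 0.01, -0.5),
               class = "cidep_invalid_input")
  expect_error(dimensionless_design(1, 5, 1, -0.5),
               class = "cidep_invalid_input")
  expect_error(dimensionless_design(1, 5, 0.01, 1.5),
               class = "cidep_invalid_input")
  expect_error(arc_position(1.2), class = "cidep_invalid_input")
})

test_that("Clausius-Mossotti factor matches limits and a direct oracle", {
  # identical particle and fluid: zero contrast at any frequency
  p <- particle_spec(1e-6, 78, 1e-2)
  f <- fluid_spec(78, 1e-2)
  expect_equal(clausius_mossotti(p, f, 1e4), 0 + 0i)

  # highly conducting particle at DC: factor tends to +1
  expect_equal(Re(clausius_mossotti(particle_spec(1e-6, 2.55, 1e4), f, 0)),
               1, tolerance = 1e-5)

  # frozen value from an independent complex-arithmetic oracle (direct
  # substitution of the defining formula with absolute permittivities)
  fcm <- clausius_mossotti(particle_spec(1e-6, 2.55, 2e-3),
                           fluid_spec(78, 1e-2), 1e3)
  expect_equal(Re(fcm), -0.363636381678, tolerance = 1e-9)
  expect_equal(Im(fcm), 4.5000251e-05, tolerance = 1e-6)

  # DC limit is conductivity-only
  expect_equal(Re(clausius_mossotti(particle_spec(1e-6, 2.55, 2e-3),
                                    fluid_spec(78, 1e-2), 0)),
               (2e-3 - 1e-2) / (2e-3 + 2e-2))
  # DC with no conduction anywhere: undefined
  expect_error(clausius_mossotti(particle_spec(1e-6, 2.55, 0),
                                 fluid_spec(78, 0), 0),
               class = "cidep_undefined_factor")
})

test_that("Clausius-Mossotti real part stays in [-0.5, 1]", {
  set.seed(7)
  for (i in 1:50) {
    p <- particle_spec(1e-6, runif(1, 1, 100), 10^runif(1, -6, 1))
    f <- fluid_spec(runif(1, 1, 100), 10^runif(1, -6, 1))
    re <- Re(clausius_mossotti(p, f, 10^runif(1, 0, 9)))
    expect_gte(re, -0.5)
    expect_lte(re, 1)
  }
})

test_that("nondimensionalisation reproduces hand-evaluated values", {
  ch <- channel_spec(width = 200e-6, mean_radius = 1e-3, wall_zeta = 0)
  pa <- particle_spec(1e-6, 2.55, 2e-3, zeta = 0.05)
  d0 <- nondimensionalize(ch, drive_spec(100), pa, fcm_real = -0.5)
  expect_equal(d0$v_app, 100 / (6 * 0.05), tolerance = 1e-12) # 333.33
  expect_equal(d0$curvature_ratio, 5)
  expect_equal(d0$blockage, 0.005)
  expect_identical(d0$ek_direction, "ccw")

  # the AC bias enters through (1 + alpha^2): alpha = 1 doubles V*App
  d1 <- nondimensionalize(ch, drive_spec(100, ac_ratio = 1), pa, -0.5)
  expect_equal(d1$v_app, 2 * d0$v_app)

  # reversing the zeta contrast flips the electrokinetic direction
  pa_rev <- particle_spec(1e-6, 2.55, 2e-3, zeta = -0.05)
  expect_identical(nondimensionalize(ch, drive_spec(100), pa_rev,
                                     -0.5)$ek_direction, "cw")

  expect_error(
    nondimensionalize(ch, drive_spec(100),
                      particle_spec(1e-6, 2.55, 2e-3, zeta = 0), -0.5),
    class = "cidep_zero_ek_velocity")
  expect_error(
    nondimensionalize(ch, drive_spec(100),
                      particle_spec(3e-4, 2.55, 2e-3, zeta = 0.05), -0.5),
    class = "cidep_blockage_infeasible")
})

test_that("dimensional voltage inverts the nondimensionalisation", {
  expect_equal(dimensional_voltage(100 / (6 * 0.05), 0, 0.05), 100,
               tolerance = 1e-12)
  expect_equal(dimensional_voltage(0, 1, 0.05), 0)
  set.seed(11)
  for (i in 1:20) {
    v0 <- runif(1, -500, 500)
    alpha <- runif(1, 0, 3)
    zd <- sample(c(-1, 1), 1) * runif(1, 1e-3, 0.2)
    v_app <- v0 * (1 + alpha^2) / (6 * zd)
    expect_equal(dimensional_voltage(v_app, alpha, zd), v0,
                 tolerance = 1e-12)
  }
})

test_that("analytic arc field is inverse-radius and inner-wall dominated", {
  d <- example_design(1, 0.01, -0.5)
  expect_equal(arc_field_magnitude(0.5, d), 0.2)       # 1/(5 - 0.5 + 0.5)
  expect_equal(arc_field_magnitude(0, d) / arc_field_magnitude(1, d),
               (5 + 0.5) / (5 - 0.5))
  set.seed(3)
  for (rc in c(0.51, runif(5, 0.6, 20))) {
    dd <- dimensionless_design(1, rc, 0.01, -0.5)
    e <- arc_field_magnitude(seq(0, 1, length.out = 50), dd)
    expect_true(all(diff(e) < 0))
  }
  expect_error(arc_field_magnitude(1.5, d), class = "cidep_invalid_input")
})
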