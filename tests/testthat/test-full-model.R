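test_that("deflection rate matches hand evaluation and reduces to the exact model", {
  # midpoint of the channel: the inner/outer wall repulsion terms cancel by
  # symmetry, leaving the pure DEP rate 3569.5 * 0.08^2 * 0.5 / 5
  d <- example_design(3569.5, 0.08, -0.5)
  expect_equal(deflection_rate(0.5, d), 2.28448, tolerance = 1e-10)
  # suppressing the wall term reproduces the point-particle rate everywhere
  r <- seq(0.05, 0.95, by = 0.1)
  exact_rate <- abs(d$v_app) * d$blockage^2 *
    (-d$fcm_real / (d$curvature_ratio + r - 0.5))
  expect_equal(deflection_rate(r, d, wall_repulsion = FALSE), exact_rate)
  expect_error(deflection_rate(0, d), class = "cidep_singular_wall")
  expect_error(deflection_rate(1, d), class = "cidep_singular_wall")
})

test_that("equilibrium coordinates match the reference values", {
  # pDEP, d* = 0.12: equilibrium near the inner wall
  eq_p <- equilibrium_coordinate(example_design(694.44, 0.12, 0.5))
  expect_equal(eq_p$r_eq, 0.098, tolerance = 5e-3)
  # nDEP, d* = 0.08: equilibrium near the outer wall
  eq_n <- equilibrium_coordinate(example_design(1562.5, 0.08, -0.5))
  expect_equal(eq_n$r_eq, 0.9244, tolerance = 1e-4)
  expect_error(equilibrium_coordinate(example_design(100, 0.05, 0)),
               class = "cidep_no_dep")
})

test_that("equilibrium residual is tiny and the rate changes sign across it", {
  for (d in random_designs(15, seed = 202)) {
    eq <- equilibrium_coordinate(d)
    expect_lt(abs(eq$residual), 1e-10)
    below <- deflection_rate(eq$r_eq * 0.99, d)
    above <- deflection_rate(eq$r_eq + 0.01 * (1 - eq$r_eq), d)
    expect_lt(below * above, 0)
    # rate is exactly balanced at the root
    expect_equal(deflection_rate(eq$r_eq, d), 0,
                 tolerance = abs(d$v_app) * d$blockage^2 * 1e-10)
  }
})

test_that("nDEP equilibrium approaches the outer wall as the particle shrinks", {
  r_eqs <- vapply(c(0.1, 0.05, 0.02, 0.01, 0.005), function(dd) {
    equilibrium_coordinate(example_design(1, dd, -0.5))$r_eq
  }, numeric(1))
  expect_true(all(diff(r_eqs) > 0))
  expect_gt(r_eqs[length(r_eqs)], 0.99)
})

test_that("focusing voltage matches the empirical correlation band", {
  # pDEP worked example: correlation predicts 1404.85 with a stated mean
  # error of 1.31%
  fv <- focusing_voltage(5, 0.08, 0.5)
  expect_equal(fv$v_app_abs, 1404.85, tolerance = 0.02)
  expect_equal(fv$quantity, fv$v_app_abs * 0.5 / 5, tolerance = 1e-12)
  # wall repulsion always lowers the requirement below the point-particle
  # threshold
  for (dd in c(0.02, 0.05, 0.08, 0.12)) {
    v_exact <- 5 / (dd^2 * 0.5)
    expect_lt(focusing_voltage(5, dd, 0.5)$v_app_abs, v_exact)
    expect_lt(focusing_voltage(5, dd, -0.5)$v_app_abs, v_exact)
    # the stronger inner-wall repulsion assists nDEP more than pDEP
    expect_lt(focusing_voltage(5, dd, -0.5)$v_app_abs,
              focusing_voltage(5, dd, 0.5)$v_app_abs)
  }
})

test_that("focusing voltage approaches the point-particle limit for small particles", {
  # pDEP: the equilibrium offset sits at the near-wall end, so the
  # quadrature converges tightly onto 1/d*^2
  expect_equal(focusing_voltage(5, 0.001, 0.5)$quantity, 1e6,
               tolerance = 5e-3)
  # nDEP: the integrand diverges logarithmically at r*Eq, so the 1% offset
  # truncates about 1% of the span near the outer wall
  expect_equal(focusing_voltage(5, 0.001, -0.5)$quantity, 1e6,
               tolerance = 2e-2)
})

test_that("focusing voltage flags infeasible offset bands", {
  expect_error(focusing_voltage(5, 0.9, 0.5, eq_offset = 0.35),
               class = "cidep_infeasible_focusing")
})

test_that("full pathline focuses realistic particles as expected per regime", {
  # small particle at the exact-solution voltage: wall repulsion is
  # negligible and the particle ends within 0.01 of the outer wall
  d1 <- example_design(400000, 0.005, -0.5)
  pl1 <- pathline_full(0.0025, 1, d1)
  expect_equal(tail(pl1$r_star, 1), 1, tolerance = 0.01)

  # large particle at the exact-solution voltage: focused onto the
  # equilibrium coordinate well before the outlet and held there
  d3 <- example_design(1562.5, 0.08, -0.5)
  pl3 <- pathline_full(0.04, 1, d3)
  late <- pl3$r_star[pl3$theta_star >= 0.95]
  expect_true(all(abs(late - 0.9244) < 1e-3))
  # monotone approach from below
  expect_true(all(diff(pl3$r_star) >= -1e-9))
})

test_that("full pathline without the wall term matches the closed form", {
  for (d in random_designs(8, seed = 303)) {
    r0 <- runif(1, 0.2, 0.8)
    ref <- pathline_exact(r0, 0.5, d)
    if (ref$wall_capture) next
    pl <- pathline_full(r0, 0.5, d, wall_repulsion = FALSE)
    expect_equal(tail(pl$r_star, 1), ref$r_end, tolerance = 1e-6)
  }
})

test_that("pathline is invariant under reversal of the EK direction", {
  d_ccw <- example_design(1562.5, 0.08, -0.5)
  d_cw <- example_design(-1562.5, 0.08, -0.5)
  p1 <- pathline_full(0.04, 1, d_ccw)
  p2 <- pathline_full(0.04, 1, d_cw)
  expect_equal(p2$r_star, p1$r_star, tolerance = 1e-12)
})
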