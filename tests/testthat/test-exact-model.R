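test_that("closed-form pathline reproduces the reference endpoints", {
  cases <- list(
    # r_start, theta_span, v_app, d_star, fcm, expected r_end, abs tol
    list(1, 1, 1404.85, 0.08,  0.5, 0.1107, 1e-4), # pDEP, outer -> inner
    list(0, 1, 3569.5,  0.05, -0.5, 0.901,  5e-4), # nDEP, inner -> outer
    list(0, 1, 12500,   0.02, -0.5, 0.5249, 1e-4), # half-voltage turn
    list(0.37, 0, 9999,  0.05, -0.5, 0.37, 1e-12)  # zero arc traversed
  )
  for (cs in cases) {
    d <- example_design(cs[[3]], cs[[4]], cs[[5]])
    res <- pathline_exact(cs[[1]], cs[[2]], d)
    expect_lt(abs(res$r_end - cs[[6]]), cs[[7]])
    expect_false(res$wall_capture)
  }
  # no DEP: pure electrokinetic transport, radius unchanged
  expect_equal(pathline_exact(0.3, 1, example_design(1e4, 0.05, 0))$r_end,
               0.3)
})

test_that("over-threshold designs are clamped and flagged as wall capture", {
  # nDEP far above the focusing threshold overshoots the outer wall
  res <- pathline_exact(0, 1, example_design(1e5, 0.05, -0.5))
  expect_true(res$wall_capture)
  expect_identical(res$wall, "outer")
  expect_equal(res$r_end, 1)
  # pDEP mirror case hits the inner wall
  res <- pathline_exact(1, 1, example_design(1e5, 0.05, 0.5))
  expect_true(res$wall_capture)
  expect_identical(res$wall, "inner")
  expect_equal(res$r_end, 0)
})

test_that("closed form agrees with brute-force ODE integration", {
  for (d in random_designs(20, seed = 101)) {
    r0 <- runif(1, 0.05, 0.95)
    got <- pathline_exact(r0, 0.7, d)
    if (got$wall_capture) next
    expect_equal(got$r_end, ode_exact_oracle(r0, 0.7, d), tolerance = 1e-8)
  }
})

test_that("DEP sign / EK direction combinations change only the solution sign", {
  # the squared-radius increment |(r2+C)^2 - (r1+C)^2| per unit angular
  # span is identical across all four sign combinations; only its sign
  # (the deflection side) changes
  cc <- 4.5
  incr <- function(r0, v, fcm) {
    r1 <- pathline_exact(r0, 0.5, example_design(v, 0.05, fcm))$r_end
    (r1 + cc)^2 - (r0 + cc)^2
  }
  ref <- incr(0, 2000, -0.5)
  expect_gt(ref, 0)
  expect_equal(incr(0, -2000, -0.5), ref, tolerance = 1e-12)  # cw EK
  expect_equal(incr(1, 2000, 0.5), -ref, tolerance = 1e-12)   # pDEP
  expect_equal(incr(1, -2000, 0.5), -ref, tolerance = 1e-12)
})

test_that("focusing identity equals 1 at threshold and scales linearly", {
  expect_equal(focusing_identity(example_design(400000, 0.005, -0.5)), 1)
  expect_equal(focusing_identity(example_design(25000, 0.02, -0.5)), 1)
  expect_equal(focusing_identity(example_design(12500, 0.02, -0.5)), 0.5)
  expect_error(focusing_identity(example_design(100, 0.05, 0)),
               class = "cidep_no_dep")
})

test_that("design thresholds reproduce the reference worked examples", {
  v_min <- function(d) design_thresholds(curvature_ratio = 5, blockage = d,
                                         fcm_abs = 0.5)$v_min
  expect_equal(v_min(0.02), 25000)
  expect_equal(v_min(0.005), 400000)
  expect_equal(v_min(0.12), 694.44, tolerance = 1e-4)
  expect_equal(v_min(0.08), 1562.5)
})

test_that("the three threshold forms are mutually consistent", {
  set.seed(5)
  for (i in 1:10) {
    rc <- runif(1, 1, 15); d <- runif(1, 0.005, 0.15)
    fcm <- runif(1, 0.05, 1)
    v <- design_thresholds(curvature_ratio = rc, blockage = d,
                           fcm_abs = fcm)$v_min
    # substituting the computed threshold back closes the identity
    expect_equal(focusing_identity(dimensionless_design(v, rc, d, fcm)),
                 1, tolerance = 1e-12)
    d_min <- design_thresholds(curvature_ratio = rc, v_app = v,
                               fcm_abs = fcm)$d_min
    expect_equal(d_min, d, tolerance = 1e-12)
    r_max <- design_thresholds(blockage = d, v_app = v,
                               fcm_abs = fcm)$r_max
    expect_equal(r_max, rc, tolerance = 1e-12)
  }
  expect_error(design_thresholds(curvature_ratio = 5, fcm_abs = 0.5),
               class = "cidep_invalid_input")
  expect_error(design_thresholds(curvature_ratio = 5, blockage = 0.02,
                                 v_app = 100, fcm_abs = 0.5),
               class = "cidep_invalid_input")
  expect_error(design_thresholds(curvature_ratio = 5, blockage = 0.02,
                                 fcm_abs = 0),
               class = "cidep_invalid_input")
})

test_that("angle_to_reach inverts the closed-form pathline", {
  d <- dimensionless_design(25000, 5, 0.02, -0.5)
  expect_equal(angle_to_reach(0, 1, d), 1, tolerance = 1e-12)
  expect_equal(angle_to_reach(0.4, 0.4, d), 0)
  # round trip against the half-voltage endpoint
  d2 <- example_design(12500, 0.02, -0.5)
  r2 <- pathline_exact(0, 1, d2)$r_end
  expect_equal(angle_to_reach(0, r2, d2), 1, tolerance = 1e-10)
  expect_error(angle_to_reach(0, 1, example_design(100, 0.02, 0)),
               class = "cidep_no_deflection")
})
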