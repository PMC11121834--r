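test_that("shape coefficient matches the classical frustum-difference route", {
  # degenerate cylinder
  expect_equal(shape_coefficient(shape_params(1, 0, 0)), pi / 4)
  cases <- list(c(0.3, 1.0, 0.9), c(0.5, 0.8, 0.6), c(1, 1.2, 0.4),
                c(0.1, 0.5, 0.2))
  for (cs in cases) {
    expect_equal(shape_coefficient(shape_params(cs[1], cs[2], cs[3])),
                 frustum_coefficient(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
})

test_that("invalid shape parameters are rejected with explanation", {
  expect_error(shape_params(0, 0.5, 0.5), "alpha")
  expect_error(shape_params(1.5, 0.5, 0.5), "alpha")
  expect_error(shape_params(0.5, -0.1, 0.5), "p0")
  expect_error(shape_params(0.5, 0.5, -1), "q0")
  # rhombus escaping the circle: 1 + q0^2 > (1 + p0)^2
  expect_error(shape_params(0.5, 0.1, 1.0), "inscribed")
})

test_that("calibration reaches the target coefficient as a fixed point", {
  sh <- calibrate_shape(0.3, 0.9, 1.21)
  expect_lt(abs(shape_coefficient(sh) - 1.21), 1e-9)
  expect_equal(sh$p0, bisect_p0(0.3, 0.9, 1.21), tolerance = 1e-9)
  expect_equal(round(sh$p0, 3), 0.970)
  # cylinder limit
  cyl <- calibrate_shape(1, 0, pi / 4)
  expect_equal(cyl$p0, 0, tolerance = 1e-9)
  # fixed point over a parameter grid; combinations whose calibrated rhombus
  # would escape the circle must be rejected, not silently returned
  for (alpha in c(0.2, 0.5, 0.8)) {
    for (q0 in c(0, 0.5, 0.9)) {
      for (target in c(0.9, 1.21, 1.5)) {
        sh <- tryCatch(calibrate_shape(alpha, q0, target),
                       error = function(e) e)
        if (inherits(sh, "error")) {
          expect_match(conditionMessage(sh), "inscribed|unreachable")
        } else {
          expect_lt(abs(shape_coefficient(sh) - target), 1e-9)
        }
      }
    }
  }
  expect_error(calibrate_shape(0.1, 0, 0.01), "unreachable")
  expect_error(calibrate_shape(0.8, 0.9, 0.9), "inscribed")
})

test_that("analytic volume matches k*D^2*L, scales correctly, splits the RVOT fraction", {
  g <- phantom_at(4.2, 7.7)
  expect_equal(analytic_volume(g), 1.21 * 4.2^2 * 7.7, tolerance = 1e-12)
  expect_equal(round(analytic_volume(g), 2), 164.35)
  # homogeneity: degree 2 in D, degree 1 in L
  c1 <- 1.7
  expect_equal(analytic_volume(phantom_at(4.2 * c1, 7.7 * c1)),
               c1^3 * analytic_volume(g), tolerance = 1e-12)
  expect_equal(analytic_volume(phantom_at(4.2 * c1, 7.7)),
               c1^2 * analytic_volume(g), tolerance = 1e-12)
  # appendage is exactly fraction f of the returned total
  gr <- phantom_at(4.2, 7.7, rvot = rvot_spec(0.19))
  expect_equal(analytic_volume(g) / analytic_volume(gr), 1 - 0.19,
               tolerance = 1e-12)
  expect_equal(round(analytic_volume(gr), 1), 202.9)
})

test_that("cross-section areas integrate to the analytic volume", {
  g0 <- phantom_geometry(shape_params(0.3, 1, 0.9), 4.2, 7.7)
  expect_equal(cross_section_area(g0, 0), (pi - 0.45) * 4.2^2,
               tolerance = 1e-12)
  expect_equal(cross_section_area(g0, g0$L),
               g0$shape$alpha^2 * cross_section_area(g0, 0),
               tolerance = 1e-12)
  expect_equal(cross_section_area(g0, -0.1), 0)
  expect_equal(cross_section_area(g0, g0$L + 0.1), 0)
  # midpoint quadrature, 1e4 steps, with and without appendage
  for (g in list(g0, phantom_at(), phantom_at(rvot = rvot_spec(0.15)))) {
    zs <- (seq_len(1e4) - 0.5) * g$L / 1e4
    quad <- sum(cross_section_area(g, zs)) * g$L / 1e4
    expect_lt(abs(quad - analytic_volume(g)) / analytic_volume(g), 1e-6)
  }
})

test_that("point membership respects the closed-solid convention", {
  g <- phantom_geometry(shape_params(0.3, 1, 0.9), 4.2, 7.7)
  r <- g$shape$beta * g$D / 2
  expect_true(contains_point(g, 0, 0, 0))
  expect_false(contains_point(g, r - 1e-6, 0, 0))    # inside the rhombus bite
  expect_true(contains_point(g, r, 0, 0))            # rhombus vertex: boundary
  expect_false(contains_point(g, 0, 0, g$L + 1e-9))  # beyond apex
  expect_true(contains_point(g, 0, 0, g$L))          # apex plane included
  expect_true(contains_point(g, 0, r, 0))            # disc boundary included
  expect_false(contains_point(g, 0, r + 1e-9, 0))
  # vectorization and recycling
  expect_identical(contains_point(g, c(0, r - 1e-6), 0, 0), c(TRUE, FALSE))
})

test_that("Monte-Carlo volume is deterministic and agrees with closed forms", {
  cyl <- phantom_geometry(shape_params(1, 0, 0), D = 2, L = 1)
  mc <- monte_carlo_volume(cyl, 2e5, seed = 99)
  expect_lt(abs(mc$volume - pi), 3 * mc$se)
  mc2 <- monte_carlo_volume(cyl, 2e5, seed = 99)
  expect_identical(mc$volume, mc2$volume)
  # random-shape sweep against k*D^2*L (coefficient identity)
  set.seed(202)
  for (i in 1:8) {
    sh <- random_shape()
    D <- runif(1, 3, 5); L <- runif(1, 6, 9)
    g <- phantom_geometry(sh, D, L)
    mc <- monte_carlo_volume(g, 2e5, seed = 300 + i)
    expect_lt(abs(mc$volume - analytic_volume(g)), 3 * mc$se)
  }
  # RVOT phantom too
  gr <- phantom_at(rvot = rvot_spec(0.19))
  mcr <- monte_carlo_volume(gr, 2e5, seed = 77)
  expect_lt(abs(mcr$volume - analytic_volume(gr)), 3 * mcr$se)
})

test_that("long-axis basal chord equals D regardless of the rhombus", {
  sec <- long_axis_section(phantom_at(4.2, 7.7))
  expect_equal(sec$basal_width, 4.2, tolerance = 1e-12)
  expect_equal(sec$apical_width, 0.3 * 4.2, tolerance = 1e-12)
  expect_equal(sec$height, 7.7)
  set.seed(41)
  for (i in 1:20) {
    sh <- random_shape()
    D <- runif(1, 2, 6)
    sec <- long_axis_section(phantom_geometry(sh, D, 8))
    expect_lt(abs(sec$basal_width - D), 1e-12)
  }
  # alpha = 1: rectangle
  rect <- long_axis_section(phantom_geometry(shape_params(1, 0.8, 0.5), 3, 5))
  expect_equal(rect$apical_width, rect$basal_width)
})

test_that("phantom records round-trip through serialization", {
  g <- phantom_at(4.1, 7.3, rvot = rvot_spec(0.12, 0.25))
  rec <- geom_to_record(g)
  g2 <- record_to_geom(rec)
  expect_equal(analytic_volume(g), analytic_volume(g2))
  expect_equal(geom_to_record(g2), rec)
  # JSON round trip
  g3 <- record_to_geom(jsonlite::fromJSON(jsonlite::toJSON(rec,
                                                           auto_unbox = TRUE,
                                                           digits = NA)))
  expect_equal(analytic_volume(g3), analytic_volume(g))
  # no appendage encodes as rvot_f = 0
  expect_equal(geom_to_record(phantom_at())$rvot_f, 0)
})
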