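test_that("the trp contour model has 5 state equations and 8 boundary species", {
  g <- trp_fixture()
  cn <- enumerate_contours(g)[[1]]
  m <- build_contour_model(cn, g)
  expect_identical(m$state$id, c("AN", "NPRAN", "CPAD5P", "IGP", "TRP"))
  expect_equal(length(m$rhs(0, m$initials, m$parameters)),
               nrow(m$state))
  expect_setequal(m$boundary$id, c("CHOR", "GLN", "PYR", "GLU", "PRPP",
                                   "PPI", "SER", "T3P1"))
  expect_equal(m$reactions[[1]]$law$form, "hill_inhibited")
  expect_identical(m$reactions[[1]]$law$inhibitor, "TRP")
  expect_true(all(vapply(m$reactions[-1], function(r) r$law$form,
                         "") == "mass_action"))
})

test_that("generated state dimension always equals the contour substance count", {
  for (k in c(2, 3, 4, 6)) {
    g <- chain_contour_graph(k)
    cn <- enumerate_contours(g)[[1]]
    m <- build_contour_model(cn, g)
    expect_equal(nrow(m$state), k)
    expect_equal(length(m$rhs(0, m$initials, m$parameters)), k)
    forms <- vapply(m$reactions, function(r) r$law$form, "")
    expect_equal(sum(forms == "hill_inhibited"), 1L)
    expect_equal(sum(forms == "mass_action"), k - 1L)
  }
})

test_that("the generated equilibrium matches the independent root bracket", {
  g <- trp_fixture()
  cn <- enumerate_contours(g)[[1]]
  # h = 1, equal k and kD: fixed point solvable by 1-D bracketing
  m <- build_contour_model(cn, g, params = list(h = 1, K = 1, kD = 0.5))
  ss <- contour_steady_state(m)
  expect_equal(max(abs(m$rhs(0, ss, m$parameters))), 0, tolerance = 1e-10)
  tr <- integrate_model(m, t_end = 200, rtol = 1e-12, atol = 1e-14)
  final <- tr$states[nrow(tr$states), ]
  expect_lt(max(abs(final - ss)), 1e-8)
})

test_that("parameter overrides are validated", {
  g <- chain_contour_graph(3)
  cn <- enumerate_contours(g)[[1]]
  expect_error(build_contour_model(cn, g, params = list(K = 0)), "K must")
  expect_error(build_contour_model(cn, g, params = list(h = 0.5)),
               "h must")
  expect_error(build_contour_model(cn, g, params = list(zz = 1)),
               "unknown parameter")
  expect_error(build_contour_model(cn, g, params = list(kD_S1 = -1)),
               "must be >= 0")
  m <- build_contour_model(cn, g, params = list(k_R2 = 2, kD_S3 = 0.05))
  expect_equal(unname(m$parameters[["k_R2"]]), 2)
  expect_equal(unname(m$parameters[["kD_S3"]]), 0.05)
  # contour/graph mismatch
  other <- trp_fixture()
  expect_error(build_contour_model(cn, other), "missing")
})

test_that("contour models keep concentrations nonnegative", {
  g <- trp_fixture()
  cn <- enumerate_contours(g)[[1]]
  m <- build_contour_model(cn, g)
  # start on the boundary of the positive orthant
  zero_start <- stats::setNames(rep(0, nrow(m$state)), m$state$id)
  tr <- integrate_model(m, t_end = 100, initials = zero_start)
  expect_gte(min(tr$states), -1e-9)
  corner <- stats::setNames(c(0, 5, 0, 5, 0), m$state$id)
  tr2 <- integrate_model(m, t_end = 100, initials = corner)
  expect_gte(min(tr2$states), -1e-9)
})

test_that("the classical registry instantiates and rejects unknowns", {
  reg <- classic_registry()
  expect_setequal(reg$name, c("lotka1910", "lotka_volterra", "van_der_pol",
                              "goodwin3", "selkov", "cicr"))
  for (nm in reg$name) {
    sys <- make_classic(nm)
    expect_s3_class(sys, "ode_system")
    d <- sys$rhs(0, sys$initials, sys$parameters)
    expect_length(d, reg$dimension[reg$name == nm])
    expect_true(all(is.finite(d)))
  }
  expect_error(make_classic("brusselator"), "registry")
  expect_error(make_classic("goodwin3", overrides = c(nope = 1)),
               "unknown parameter")
  expect_error(make_classic("goodwin3", initials = c(zz = 1)),
               "unknown state")
})

test_that("the predator-prey first integral is conserved along orbits", {
  sys <- make_classic("lotka_volterra")
  tr <- integrate_model(sys, t_end = 50)
  inv <- lotka_volterra_invariant(tr, sys$parameters)
  expect_lt(max(abs(inv - inv[1])), 1e-6)
})

test_that("the harmonic limit of the relaxation oscillator has period 2*pi/omega", {
  for (omega in c(1, 2)) {
    sys <- make_classic("van_der_pol", overrides = c(alpha = 0,
                                                     omega = omega))
    tr <- integrate_model(sys, t_end = 80 / omega, n_points = 8000)
    rep <- detect_oscillation(tr)
    expect_equal(rep$period, 2 * pi / omega, tolerance = 0.005)
  }
})

test_that("the relaxation-oscillator period matches a reference integration", {
  sys <- make_classic("van_der_pol")  # alpha = 1, omega = 1
  # oracle: dense, high-accuracy integration, successive-peak timing
  dense <- integrate_model(sys, t_end = 200, n_points = 20000,
                           rtol = 1e-11, atol = 1e-12)
  p_ref <- oracle_period(dense$times, dense$states[, "x"])
  rep <- detect_oscillation(integrate_model(sys, t_end = 150))
  expect_equal(rep$overall_label, "sustained")
  expect_equal(rep$period, p_ref, tolerance = 0.01)
})
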