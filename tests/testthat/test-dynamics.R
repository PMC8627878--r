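test_that("integration reproduces closed forms and flags divergence", {
  decay <- ode_system("decay", function(t, y, p) -p[["r"]] * y,
                      c(r = 1), c(x = 1), default_tend = 5)
  tr <- integrate_model(decay, t_end = 5, n_points = 501)
  i1 <- which.min(abs(tr$times - 1))
  expect_equal(unname(tr$states[i1, "x"]), exp(-1), tolerance = 1e-6)
  expect_false(tr$diverged)
  expect_error(integrate_model(decay, t_end = -1), "t_end")

  blow <- ode_system("blowup", function(t, y, p) y^2, c(a = 1),
                     c(x = 1), default_tend = 2)
  tr2 <- integrate_model(blow, t_end = 2, n_points = 500)
  expect_true(tr2$diverged)
  expect_lt(max(tr2$times), 2)
  expect_true(all(is.finite(tr2$states)))
})

test_that("trajectory CSV export is faithful", {
  tr <- integrate_model(damped_harmonic(), t_end = 10, n_points = 200)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tf)
  back <- utils::read.csv(tf)
  expect_named(back, c("time", "x", "v"))
  expect_equal(back$x, unname(tr$states[, "x"]), tolerance = 1e-12)
})

test_that("classifier labels the canonical regimes", {
  expect_equal(detect_oscillation(
    integrate_model(constant_system()))$overall_label, "steady")
  expect_equal(detect_oscillation(
    integrate_model(damped_harmonic()))$overall_label, "damped")
  vdp <- detect_oscillation(integrate_model(make_classic("van_der_pol")))
  expect_equal(vdp$overall_label, "sustained")
  expect_gte(min(vdp$variables$n_peaks), 5)
  expect_lte(max(vdp$variables$period_cv, na.rm = TRUE), 0.05)
})

test_that("classifier is deterministic and validates its input", {
  tr <- integrate_model(make_classic("selkov"))
  r1 <- detect_oscillation(tr)
  r2 <- detect_oscillation(tr)
  expect_identical(r1$variables, r2$variables)
  short <- integrate_model(constant_system(), t_end = 1, n_points = 50)
  expect_error(detect_oscillation(short), "fewer than 100")
  expect_error(detection_settings(transient_frac = 1.2))
  expect_error(detect_oscillation(list()), "trajectory")
})

test_that("report files serialize the classification", {
  rep <- detect_oscillation(integrate_model(make_classic("van_der_pol")))
  tf_json <- withr::local_tempfile(fileext = ".json")
  tf_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, tf_json)
  write_report(rep, tf_tsv)
  j <- jsonlite::read_json(tf_json)
  expect_equal(j$overall_label, "sustained")
  expect_equal(length(j$variables), 2L)
  tab <- utils::read.delim(tf_tsv)
  expect_equal(tab$label, rep$variables$label)
})

test_that("phase portraits close for limit cycles and collapse at rest", {
  steady <- integrate_model(damped_harmonic(), t_end = 300)
  pp0 <- phase_portrait(steady, "x", "v")
  expect_lt(attr(pp0, "orbit_diameter"), 1e-4)

  vdp <- integrate_model(make_classic("van_der_pol"))
  pp <- phase_portrait(vdp, "x", "v")
  expect_lt(attr(pp, "return_distance"),
            0.05 * attr(pp, "orbit_diameter"))
  expect_error(phase_portrait(vdp, "x", "nope"), "unknown variable")
})

test_that("the goodwin loop's oscillatory region is an up-set in h", {
  sc <- scan_parameters(make_classic("goodwin3"),
                        h_values = c(2, 4, 6, 8, 10, 12, 14))
  expect_false(any(sc$sustained[sc$h <= 8]))
  expect_true(all(sc$sustained[sc$h >= 12]))
  # up-set: once sustained, sustained for all larger h
  first <- match(TRUE, sc$sustained)
  if (!is.na(first)) expect_true(all(sc$sustained[seq(first, nrow(sc))]))
  expect_error(scan_parameters(make_classic("goodwin3"),
                               h_values = numeric()), "empty")
  expect_error(scan_parameters(make_classic("goodwin3"), h_values = 0.5),
               ">= 1")
  expect_error(scan_parameters(make_classic("lotka1910"), h_values = 2),
               "no Hill exponent")
})
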