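# Power law, gyroid calibration fit, infill matching, print parameters.

test_that("the power law evaluates and inverts exactly", {
  m <- power_law()
  expect_equal(power_law_eval(m, 0.158), 149.784, tolerance = 1e-12)
  expect_equal(power_law_eval(m, 1), 6000)
  expect_equal(power_law_eval(m, 0), 0)
  expect_equal(power_law_invert(m, 6000), 1)
  expect_equal(power_law_invert(m, power_law_eval(m, 0.37)), 0.37,
               tolerance = 1e-12)
  expect_equal(power_law_invert(m, 155), sqrt(155 / 6000), tolerance = 1e-12)
  expect_error(power_law_eval(m, 1.2), "\\[0, 1\\]")
  expect_error(power_law_invert(m, 7000), "e_bone")
  expect_error(power_law(e_bone = -1), "positive")
})

test_that("the log-log fit recovers an exact power model", {
  rho <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  cal <- fit_gyroid_curve(rho, 2000 * rho^1.5)
  expect_equal(unname(coef(cal)["a"]), 2000, tolerance = 1e-9)
  expect_equal(unname(coef(cal)["g"]), 1.5, tolerance = 1e-9)
  expect_equal(max(abs(residuals(cal))), 0, tolerance = 1e-10)
  expect_error(fit_gyroid_curve(0.1, 10), "two distinct")
  expect_error(fit_gyroid_curve(c(0.1, 0.2), c(-1, 5)), "positive")
})

test_that("the fit through the three cube points matches hand OLS", {
  pts <- reference_gyroid_points()
  expect_equal(pts$infill, c(0.10, 0.20, 0.40))
  cal <- fit_gyroid_curve(pts)
  # independent closed-form OLS of log(E) on log(rho)
  x <- log(pts$infill); y <- log(pts$modulus)
  g_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hat <- exp(mean(y) - g_hat * mean(x))
  expect_equal(unname(coef(cal)["g"]), g_hat, tolerance = 1e-12)
  expect_equal(unname(coef(cal)["a"]), a_hat, tolerance = 1e-12)
  expect_equal(g_hat, 1.77, tolerance = 0.01)
  expect_equal(a_hat, 1.5e3, tolerance = 0.01)
  # fitted curve strictly increasing on (0, 1]
  rr <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(predict(cal, rr)) > 0))
})

test_that("infill matching reproduces the printed assignments", {
  cal <- fit_gyroid_curve(reference_gyroid_points())
  expect_equal(match_infill(35.6, cal)$infill_percent, 12L)   # OB foam
  expect_equal(match_infill(60, cal)$infill_percent, 16L)
  expect_equal(match_infill(150, cal)$infill_percent, 27L)
  # prefactor inverts to 100%
  expect_equal(match_infill(coef(cal)["a"], cal)$infill_percent, 100L)
  # self-consistency: each calibration point maps back to its own infill
  for (i in seq_len(3)) {
    got <- match_infill(cal$points$modulus[i], cal)$infill_percent
    expect_lte(abs(got - 100 * cal$points$infill[i]), 1)
  }
})

test_that("matching is monotone and flags extrapolation", {
  cal <- fit_gyroid_curve(reference_gyroid_points())
  es <- seq(1, 400, by = 7)
  pct <- vapply(es, function(e) match_infill(e, cal)$infill_percent,
                integer(1))
  expect_true(all(diff(pct) >= 0))
  expect_true(match_infill(5, cal)$extrapolated)
  expect_true(match_infill(400, cal)$extrapolated)
  expect_false(match_infill(100, cal)$extrapolated)
})

test_that("bvtv-driven recommendation chains power law and matching", {
  cal <- fit_gyroid_curve(reference_gyroid_points())
  rec <- infill_from_bvtv(0.158, cal = cal)
  expect_equal(rec$target_modulus, 149.784, tolerance = 1e-12)
  expect_equal(rec$infill_percent, 27L)
  expect_equal(rec$provenance, "bvtv_via_power_law")
  # degenerate: zero density clamps to the 1% floor, flagged extrapolated
  rec0 <- infill_from_bvtv(0, cal = cal)
  expect_equal(rec0$target_modulus, 0)
  expect_equal(rec0$infill_percent, 1L)
  expect_true(rec0$extrapolated)
  # chaining equals the manual two-step composition
  set.seed(6)
  for (bv in runif(5)) {
    manual <- match_infill(power_law_eval(power_law(), bv), cal)
    expect_equal(infill_from_bvtv(bv, cal = cal)$infill_percent,
                 manual$infill_percent)
  }
  # monotone in bvtv
  pct <- vapply(seq(0.02, 0.9, by = 0.02),
                function(b) infill_from_bvtv(b, cal = cal)$infill_percent,
                integer(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("with k = g the infill scales as a power of bvtv", {
  # exact self-similar case: calibration curve with the same exponent as the
  # bone power law makes infill proportional to bvtv^(k/g) = bvtv
  rho <- c(0.1, 0.2, 0.4)
  cal <- fit_gyroid_curve(rho, 3000 * rho^2)
  m <- power_law(e_bone = 6000, k = 2)
  f1 <- infill_from_bvtv(0.1, m, cal)$infill_fraction
  f2 <- infill_from_bvtv(0.2, m, cal)$infill_fraction
  expect_equal(f2 / f1, 2, tolerance = 1e-9)
})

test_that("cube-test modulus recovery matches the closed form", {
  # 10 mm cube, exactly linear F = 90.6 u -> E = 90.6 * 10 / 100 = 9.06 MPa
  u <- seq(0, 0.5, by = 0.005)
  expect_equal(modulus_from_cube_test(cube_test_record(10, fd_curve(u, 90.6 * u))),
               9.06, tolerance = 1e-9)
  # 30 mm cube: modulus = slope / 30
  expect_equal(modulus_from_cube_test(cube_test_record(30, fd_curve(u, 600 * u))),
               20, tolerance = 1e-9)
  # toe region prepended to a known linear segment: within 2%
  ct <- make_cube_curve(50, edge = 30, toe_span = 0.3, max_strain = 0.05)
  expect_equal(modulus_from_cube_test(ct$record), 50, tolerance = 0.02)
  expect_error(modulus_from_cube_test(
    cube_test_record(10, fd_curve(rep(0, 20), seq_len(20)))), "zero displacement")
})

test_that("print-parameter reports are fixed apart from the spongiosa infill", {
  cal <- fit_gyroid_curve(reference_gyroid_points())
  r16 <- print_parameter_report(match_infill(60, cal))
  expect_equal(r16$spongiosa$infill_density_percent, 16L)
  expect_equal(r16$spongiosa$infill_pattern, "gyroid")
  expect_equal(r16$spongiosa$perimeter, 0L)
  expect_equal(r16$cortex$infill_pattern, "linear")
  expect_equal(r16$cortex$infill_density_percent, 100L)
  expect_equal(r16$cortex$ew_outer_contour_mm, 0.6)
  expect_equal(r16$cortex$ew_infill_mm, 0.45)
  expect_equal(r16$global$perimeter, 2L)
  expect_equal(r16$global$printing_temperature_c, 225L)
  # determinism: identical recommendations render byte-identically
  expect_identical(format(print_parameter_report(16L)),
                   format(print_parameter_report(match_infill(60, cal))))
  # single-field dependence
  d <- format(print_parameter_report(27L)) != format(print_parameter_report(16L))
  expect_equal(sum(d), 1L)
})
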