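# Frozen high-precision reference values for the default parse, computed
# with exact rational arithmetic before implementation.
B_78_52 <- 357.38688124247145
B_MEAN <- 314.79491646382612    # R = 7.75 mm, t = 549.9 um
B_THICK <- 223.79521292249437   # R = 7.75 mm, t = 650 um
C_MEAN <- 176.58525545678243
C_78_52 <- 189.57669954435407
C_THICK <- 148.39086178882438

mean_geo <- function() cornea_geometry(7.75, 549.9)

test_that("shell coefficients match high-precision reference values", {
  expect_equal(b_coefficient(cornea_geometry(7.8, 520)), B_78_52,
               tolerance = 1e-12)
  expect_equal(b_coefficient(mean_geo()), B_MEAN, tolerance = 1e-12)
  expect_equal(c_coefficient(mean_geo()), C_MEAN, tolerance = 1e-12)
  expect_equal(c_coefficient(cornea_geometry(7.8, 520)), C_78_52,
               tolerance = 1e-12)
})

test_that("coefficients agree with an independently factored evaluation on a grid", {
  set.seed(42)
  for (i in 1:100) {
    R <- runif(1, 6.8, 9.2)
    t_um <- runif(1, 380, 720)
    geo <- cornea_geometry(R, t_um)
    expect_equal(b_coefficient(geo), oracle_b(R, t_um / 1000),
                 tolerance = 1e-12)
    expect_equal(c_coefficient(geo), oracle_c(R, t_um / 1000),
                 tolerance = 1e-12)
  }
})

test_that("coefficient structure: nu enters B only through sqrt(1 - nu^2), A halves C", {
  geo <- mean_geo()
  b0 <- b_coefficient(geo, model_constants(poisson_ratio = 0))
  b49 <- b_coefficient(geo, model_constants(poisson_ratio = 0.49))
  expect_equal(b0 / b49, 1 / sqrt(1 - 0.49^2), tolerance = 1e-12)
  c1 <- c_coefficient(geo, model_constants(applanation_area = 7.35))
  c2 <- c_coefficient(geo, model_constants(applanation_area = 14.7))
  expect_equal(c1 / c2, 2, tolerance = 1e-12)
})

test_that("coefficients decrease strictly with thickness at fixed radius", {
  ts <- seq(400, 700, by = 25)
  b <- vapply(ts, function(t) b_coefficient(cornea_geometry(7.75, t)),
              numeric(1))
  cc <- vapply(ts, function(t) c_coefficient(cornea_geometry(7.75, t)),
               numeric(1))
  expect_true(all(diff(b) < 0))
  expect_true(all(diff(cc) < 0))
})

test_that("geometry validation rejects impossible corneas and warns off-range", {
  expect_error(cornea_geometry(-7.75, 549.9), "invalid geometry")
  expect_error(cornea_geometry(7.75, 0), "invalid geometry")
  expect_error(cornea_geometry(0.5, 600), "invalid geometry")  # t >= R
  expect_warning(cornea_geometry(10.5, 549.9), "plausible")
  expect_warning(cornea_geometry(7.75, 300), "plausible")
  expect_error(model_constants(applanation_area = 0), "invalid constants")
})

test_that("ioptcalc reproduces frozen values and the calibration identity", {
  cal <- calibration_cornea(mean_geo())
  thick <- shell_coefficients(cornea_geometry(7.75, 650))
  expect_equal(ioptcalc(15, thick, cal, variant = "printed"),
               19.2095612135675, tolerance = 1e-12)
  expect_equal(ioptcalc(15, thick, cal, variant = "consistency"),
               12.0073225492863, tolerance = 1e-12)
  # identity at the calibration cornea, both variants, several pressures
  for (g in c(8, 15.06, 31)) {
    expect_identical(ioptcalc(g, cal$coefficients, cal, "printed"), g)
    expect_identical(ioptcalc(g, cal$coefficients, cal, "consistency"), g)
  }
  expect_error(ioptcalc(-3, thick, cal), "must be > 0")
})

test_that("consistency variant lowers corrected IOP for thick corneas, printed raises it", {
  cal <- calibration_cornea(mean_geo())
  thick <- shell_coefficients(cornea_geometry(7.75, 650))
  thin <- shell_coefficients(cornea_geometry(7.75, 460))
  expect_lt(ioptcalc(15, thick, cal, "consistency"), 15)
  expect_gt(ioptcalc(15, thin, cal, "consistency"), 15)
  expect_gt(ioptcalc(15, thick, cal, "printed"), 15)
})

test_that("ecalc matches the worked example and reduces algebraically at calibration", {
  cal <- calibration_cornea(mean_geo())
  est <- ecalc(15.06, 16.89, cal$coefficients)
  expect_equal(est$value, 0.234438196970689, tolerance = 1e-12)
  expect_false(est$negative_flag)
  g <- 12.5
  expect_equal(ecalc(g, g, cal$coefficients)$value,
               g * (B_MEAN - C_MEAN) / 7500, tolerance = 1e-12)
  zero <- ecalc(0, 0, cal$coefficients)
  expect_identical(zero$value, 0)
  expect_true(zero$negative_flag)
})

test_that("negative modulus values are flagged, retained, never clamped", {
  cal <- calibration_cornea(mean_geo())
  est <- ecalc(10, 30, cal$coefficients)  # C*IOPT > B*IOPG
  expect_true(est$negative_flag)
  expect_lt(est$value, 0)
})

test_that("eiopg composes ecalc with ioptcalc and is linear in the Goldmann reading", {
  cal <- calibration_cornea(mean_geo())
  expect_equal(eiopg(15.06, cal$coefficients, cal)$value,
               0.277524999302144, tolerance = 1e-12)
  test <- shell_coefficients(cornea_geometry(7.9, 510))
  e1 <- eiopg(14, test, cal)$value
  e2 <- eiopg(28, test, cal)$value
  expect_equal(e2 / e1, 2, tolerance = 1e-12)
  # definitional: eiopg == ecalc at the calculated true pressure
  iopt_hat <- ioptcalc(14, test, cal)
  expect_equal(e1, ecalc(14, iopt_hat, test)$value, tolerance = 1e-15)
})

test_that("stiffness is the exact thickness-modulus product", {
  expect_equal(stiffness(0.5499, 0.29), 0.159471, tolerance = 1e-12)
  expect_equal(stiffness(0.550, 0.25), 0.1375, tolerance = 1e-12)
  expect_identical(stiffness(0.52, 0), 0)
  expect_error(stiffness(0, 0.3), "must be > 0")
})

test_that("predicted_iopg inverts ecalc and has the modulus-free limit", {
  set.seed(7)
  for (i in 1:50) {
    geo <- random_geometry()
    coeff <- shell_coefficients(geo)
    T_iop <- runif(1, 8, 30)
    E <- runif(1, 0.05, 0.6)
    g <- predicted_iopg(T_iop, E, coeff)
    expect_equal(ecalc(g, T_iop, coeff)$value, E, tolerance = 1e-10)
  }
  coeff <- shell_coefficients(mean_geo())
  expect_equal(predicted_iopg(20, 0, coeff), coeff$c * 20 / coeff$b,
               tolerance = 1e-12)
})

test_that("moduli rescale inversely with the pressure divisor; ioptcalc is unaffected", {
  cal_a <- calibration_cornea(mean_geo(), model_constants())
  cal_b <- calibration_cornea(mean_geo(), model_constants(mmhg_per_mpa = 15000))
  test_a <- shell_coefficients(cornea_geometry(7.9, 600))
  expect_equal(ecalc(15, 17, test_a, model_constants())$value /
                 ecalc(15, 17, test_a, model_constants(mmhg_per_mpa = 15000))$value,
               2, tolerance = 1e-12)
  expect_equal(ioptcalc(15, test_a, cal_a), ioptcalc(15, test_a, cal_b),
               tolerance = 1e-15)
})

test_that("ecalc decreases strictly with thickness at fixed radius and pressures", {
  ts <- seq(450, 700, by = 10)
  e <- vapply(ts, function(t)
    ecalc(15.06, 16.89, shell_coefficients(cornea_geometry(7.75, t)))$value,
    numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("parse audit accepts only the default parse combination", {
  audit <- audit_parses()
  default_row <- audit$b_parse == "default" & audit$c_parse == "default"
  expect_true(audit$accepted[default_row])
  expect_false(any(audit$accepted[!default_row]))
  # the coefficient-C misreadings imply an implausibly stiff cornea
  c_alts <- audit$b_parse == "default" & audit$c_parse != "default"
  expect_true(all(audit$ecalc_mpa[c_alts] > 0.5))
})

test_that("keratometric dioptres convert through the 337.5 index", {
  expect_equal(keratometry_to_radius(43.55), 337.5 / 43.55, tolerance = 1e-15)
  expect_equal(keratometry_to_radius(43.55), 7.7497, tolerance = 1e-4)
  expect_error(keratometry_to_radius(0), "must be > 0")
})
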