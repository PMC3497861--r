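test_that("quadratic loss law: scaling, sign, and the He/O2 20 l/min drop", {
  A <- default_resistor_area()
  rp50 <- parabolic_resistor(132.9, A)
  he <- heliox()
  q <- lpm_to_m3s(20)
  # drop equals the equivalent-resistance reading: R * Q in clinical units
  dp <- resistor_pressure_drop(rp50, he, q)
  R <- equivalent_linear_resistance(rp50, he, q)
  expect_equal(pa_to_cmh2o(dp), R * m3s_to_lps(q))
  expect_equal(pa_to_cmh2o(dp), 4.24, tolerance = 5e-3) # ~12.7 cmH2O.s/l x 1/3 l/s
  # zero flow, quadratic flow scaling, linear density scaling, antisymmetry
  expect_identical(resistor_pressure_drop(rp50, he, 0), 0)
  expect_equal(resistor_pressure_drop(rp50, he, 2 * q),
               4 * resistor_pressure_drop(rp50, he, q))
  denser <- gas_mixture(c(He = 0.78, O2 = 0.22), pressure = 2 * 101325)
  expect_equal(resistor_pressure_drop(rp50, denser, q), 2 * dp)
  expect_equal(resistor_pressure_drop(rp50, he, -q), -dp)
})

test_that("equivalent linear resistance is homogeneous in flow and density", {
  A <- default_resistor_area()
  r <- parabolic_resistor(21.5, A)
  air <- medical_air()
  expect_equal(equivalent_linear_resistance(r, air, lpm_to_m3s(60)) /
                 equivalent_linear_resistance(r, air, lpm_to_m3s(20)), 3)
  he <- heliox()
  expect_equal(equivalent_linear_resistance(r, he, lpm_to_m3s(40)) /
                 equivalent_linear_resistance(r, air, lpm_to_m3s(40)),
               density_ratio(he, air))
  expect_error(equivalent_linear_resistance(r, air, 0), "positive")
})

test_that("area calibration inverts the loss law and is internally consistent", {
  air <- medical_air()
  A <- calibrate_area(132.9, air, lpm_to_m3s(60), 108.4)
  expect_equal(A, 8.66e-5, tolerance = 1e-3) # ~10.5 mm diameter orifice
  # round trip to machine precision
  r <- parabolic_resistor(132.9, A)
  expect_equal(equivalent_linear_resistance(r, air, lpm_to_m3s(60)), 108.4,
               tolerance = 1e-12)
  # calibrating from a different table cell gives the same area within
  # the printed two-significant-figure rounding (0.3%)
  A2 <- calibrate_area(132.9, air, lpm_to_m3s(20), 36.1)
  expect_equal(A2, A, tolerance = 3e-3)
  expect_error(calibrate_area(-1, air, 1e-3, 100), "positive")
})

test_that("one calibrated area reproduces the whole published resistance table", {
  tab <- printed_resistance_table()
  A <- default_resistor_area()
  air <- medical_air(); he <- heliox()
  for (i in seq_len(nrow(tab))) {
    r <- parabolic_resistor(tab$k[i], A)
    q <- lpm_to_m3s(tab$flow_lpm[i])
    for (cell in list(c("air", tab$air[i]), c("heo2", tab$heo2[i]))) {
      gas <- if (cell[1] == "air") air else he
      R <- equivalent_linear_resistance(r, gas, q)
      printed <- as.numeric(cell[2])
      # two-significant-figure printing: 3% relative or half a last digit
      expect_lt(abs(R - printed), max(0.03 * printed, 0.0500001))
    }
  }
})

test_that("zero-intercept quadratic fit recovers generating coefficients", {
  air <- medical_air()
  q <- lpm_to_m3s(seq(5, 60, by = 5))
  # exact polynomial data
  curve <- pressure_flow_curve(q, 2 * q + 5 * q^2, air)
  fit <- suppressWarnings(fit_pressure_flow_polynomial(curve)) # exact data
  expect_equal(fit$c1, 2, tolerance = 1e-9)
  expect_equal(fit$c2, 5, tolerance = 1e-9)
  # purely inertial data: c1 ~ 0, c2 = beta * rho
  beta <- 7e7
  rho <- mixture_density(air)
  curve2 <- pressure_flow_curve(q, beta * rho * q^2, air)
  fit2 <- suppressWarnings(fit_pressure_flow_polynomial(curve2))
  expect_equal(fit2$c1, 0, tolerance = 1e-6 * beta * rho * max(q))
  expect_equal(fit2$c2, beta * rho, tolerance = 1e-9 * beta * rho)
  expect_error(fit_pressure_flow_polynomial(
    pressure_flow_curve(q[1:2], q[1:2], air)), "3 distinct")
})

test_that("fitted coefficients of noisy curves fall within 3 standard errors", {
  set.seed(42)
  air <- medical_air()
  q <- lpm_to_m3s(seq(5, 60, by = 5))
  dp0 <- 2e4 * q + 6e7 * q^2
  sigma <- 0.01 * max(dp0)
  n_bad <- 0L
  for (rep in 1:100) {
    curve <- pressure_flow_curve(q, pmax(dp0 + rnorm(length(q), sd = sigma), 0), air)
    fit <- fit_pressure_flow_polynomial(curve)
    if (abs(fit$c1 - 2e4) > 3 * fit$coef_se[1] ||
        abs(fit$c2 - 6e7) > 3 * fit$coef_se[2]) n_bad <- n_bad + 1L
  }
  # ~0.3% expected outside +/-3 se per coefficient; allow a generous margin
  expect_lt(n_bad, 6L)
})

test_that("circuit models: density transfer, per-gas fits, error cases", {
  air <- medical_air(); he <- heliox()
  mod <- circuit_loss_model(k_fs = 1.2, k_cct = 5.0)
  expect_identical(circuit_pressure_drop(mod, air, 0), 0)
  q <- lpm_to_m3s(30)
  expect_equal(circuit_pressure_drop(mod, he, q) /
                 circuit_pressure_drop(mod, air, q),
               density_ratio(he, air))
  expect_equal(circuit_pressure_drop(mod, air, -q),
               -circuit_pressure_drop(mod, air, q))
  # polynomial model reproduces its fitted points and refuses other gases
  qs <- lpm_to_m3s(seq(10, 60, by = 10))
  curve <- pressure_flow_curve(qs, 1e4 * qs + 5e7 * qs^2, air)
  pmod <- suppressWarnings(fit_pressure_flow_polynomial(curve)) # noiseless fit
  expect_equal(circuit_pressure_drop(pmod, air, qs[3]),
               1e4 * qs[3] + 5e7 * qs[3]^2, tolerance = 1e-8)
  expect_error(circuit_pressure_drop(pmod, he, qs[3]), "fitted for gas")
})

test_that("inertial collapse statistic detects viscous contamination", {
  air <- medical_air(); he <- heliox()
  q <- lpm_to_m3s(seq(5, 60, by = 5))
  beta <- 6e7
  inertial <- function(gas) pressure_flow_curve(
    q, beta * mixture_density(gas) * q^2, gas)
  res0 <- inertial_collapse_check(list(inertial(air), inertial(he)))
  expect_equal(res0$slope, beta, tolerance = 1e-9)
  expect_lt(res0$scatter, 1e-12)
  # adding a viscous term alpha*Q breaks the collapse, increasingly with alpha
  contaminated <- function(alpha) inertial_collapse_check(lapply(
    list(air, he), function(g) pressure_flow_curve(
      q, alpha * q + beta * mixture_density(g) * q^2, g)))
  alpha_ref <- beta * mixture_density(air) * max(q) # viscous ~ inertial at max flow
  s_small <- contaminated(alpha_ref / 10)$scatter
  s_large <- contaminated(alpha_ref)$scatter
  expect_gt(s_small, 1e-6)
  expect_gt(s_large, s_small)
  # degenerate single-curve input still yields the slope
  expect_equal(inertial_collapse_check(inertial(air))$slope, beta,
               tolerance = 1e-9)
})

test_that("pressure-flow CSV round trip preserves the curve", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# bench circuit, dry air",
               "flow_lpm,dp_cmh2o", "10,0.4", "30,2.1", "60,7.9"), path)
  curve <- read_pressure_flow_csv(path, medical_air(), label = "circuit")
  expect_equal(curve$flow, lpm_to_m3s(c(10, 30, 60)))
  expect_equal(curve$pressure_drop, cmh2o_to_pa(c(0.4, 2.1, 7.9)))
})
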