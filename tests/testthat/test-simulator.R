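test_that("inspiratory split honours symmetry and quadratic-loss balance", {
  A <- default_resistor_area()
  # identical chambers: exact halves
  sym <- make_test_system(k_right = 3.3, volume_left = 0.2, volume_right = 0.2)
  q <- solve_inspiratory_split(sym, 1.0)
  expect_equal(unname(q), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(q), 1.0, tolerance = 1e-12)
  # empty chambers, no sensor loss: flow ratio set purely by sqrt(k_R/k_L)
  asym <- lung_system(
    left = lung_chamber(0.05, parabolic_resistor(3.3, A), k_fs = 0),
    right = lung_chamber(0.05, parabolic_resistor(132.9, A), k_fs = 0),
    gas = medical_air())
  q2 <- solve_inspiratory_split(asym, 1.0)
  expect_equal(q2[["left"]] / q2[["right"]], sqrt(132.9 / 3.3),
               tolerance = 1e-9)
  # no flow, equal pressures: nothing moves
  expect_equal(unname(solve_inspiratory_split(sym, 0)), c(0, 0))
  # the split equalises Y-piece pressures (common-pressure invariant)
  st <- make_test_system(volume_left = 0.3, volume_right = 0.1)
  qq <- solve_inspiratory_split(st, 0.8)
  rho <- mixture_density(st$gas)
  y_pressure <- function(side, qi) {
    ch <- st[[side]]
    u <- lps_to_m3s(qi) / st$area
    ch$volume / ch$compliance +
      pa_to_cmh2o(resistor_pressure_drop(ch$resistor, st$gas, lps_to_m3s(qi)) +
                    0.5 * ch$k_fs * rho * u * abs(u))
  }
  expect_equal(y_pressure("left", qq[["left"]]),
               y_pressure("right", qq[["right"]]), tolerance = 1e-8)
})

test_that("expiratory solver matches the decoupled closed form and symmetry", {
  A <- default_resistor_area()
  gas <- heliox()
  rho <- mixture_density(gas)
  # k_cct = 0 decouples the chambers: each flow has a closed form
  sys <- lung_system(
    left = lung_chamber(0.05, parabolic_resistor(3.3, A), k_fs = 1.2,
                        volume = 0.4),
    right = lung_chamber(0.02, parabolic_resistor(132.9, A), k_fs = 1.2,
                         volume = 0.1),
    gas = gas, circuit = circuit_loss_model(k_fs = 1.2, k_cct = 0, area = A))
  q <- solve_expiratory_flows(sys)
  closed <- function(ch) {
    P <- cmh2o_to_pa(ch$volume / ch$compliance)
    K <- ch$resistor$k / ch$resistor$area^2 + ch$k_fs / A^2
    m3s_to_lps(sqrt(2 * P / (rho * K)))
  }
  expect_equal(q[["left"]], closed(sys$left), tolerance = 1e-10)
  expect_equal(q[["right"]], closed(sys$right), tolerance = 1e-10)
  # symmetric chambers and state expire identically through a shared circuit
  sym <- make_test_system(k_right = 3.3, volume_left = 0.3, volume_right = 0.3)
  qs <- solve_expiratory_flows(sym)
  expect_equal(qs[["left"]], qs[["right"]], tolerance = 1e-12)
  # both chambers empty: no flow
  empty <- make_test_system()
  expect_equal(unname(solve_expiratory_flows(empty)), c(0, 0))
})

test_that("an empty chamber shows pendelluft inflow through a shared circuit", {
  sys <- make_test_system(k_right = 132.9, volume_left = 0.5,
                          volume_right = 0)
  q <- solve_expiratory_flows(sys)
  expect_gt(q[["left"]], 0)
  expect_lt(q[["right"]], 0) # gas pushed into the empty chamber
  # with pendelluft disabled the empty chamber is clamped to zero flow
  sys2 <- make_test_system(k_right = 132.9, volume_left = 0.5,
                           volume_right = 0, allow_pendelluft = FALSE)
  q2 <- solve_expiratory_flows(sys2)
  expect_identical(q2[["right"]], 0)
  expect_gt(q2[["left"]], 0)
})

test_that("advance steps the breath clock and conserves/clamps volume", {
  st <- ventilator_settings(1.0, 20)
  sym <- make_test_system(k_right = 3.3)
  dt <- 1e-3
  s1 <- advance(sym, st, dt)
  step <- attr(s1, "step")
  expect_equal(step$phase, "inspiration")
  # symmetric inspiration: each chamber gains q_tot*dt/2
  expect_equal(s1$left$volume, 0.5 * 1.0 * dt, tolerance = 1e-12)
  expect_equal(s1$right$volume, s1$left$volume)
  # an empty chamber in expiration stays clamped at zero without pendelluft
  ex <- make_test_system(volume_left = 0, volume_right = 0,
                         allow_pendelluft = FALSE)
  ex$time <- 1.5 # inside expiration
  e1 <- advance(ex, st, dt)
  expect_identical(e1$left$volume, 0)
  expect_identical(e1$right$volume, 0)
})

test_that("explicit stepping converges at first order in dt", {
  # partial expiration of an asymmetric state, stopped before emptying so
  # the end state is dt-sensitive
  mid_exp <- function(dt) {
    sys <- make_test_system(volume_left = 0.4, volume_right = 0.3)
    tr <- simulate_expiration(sys, 0.3, dt = dt)
    n <- nrow(tr)
    c(tr$v_left_l[n], tr$v_right_l[n])
  }
  v4 <- mid_exp(4e-3); v2 <- mid_exp(2e-3); v1 <- mid_exp(1e-3)
  err4 <- max(abs(v4 - v1)); err2 <- max(abs(v2 - v1))
  expect_gt(err4, 0)
  # halving dt roughly halves the error (first-order quadrature)
  expect_lt(err2, 0.75 * err4)
})

test_that("simulated single-chamber emptying matches the quadratic-drag closed form", {
  A <- default_resistor_area()
  gas <- heliox()
  k_tot <- 132.9
  cf <- single_chamber_emptying(0.05, k_tot, A, gas, 0.3335, dt = 1e-3)
  expect_equal(cf$t_empty, 1.5947, tolerance = 1e-4)
  # lone chamber, all loss in the branch, lossless circuit
  sys <- lung_system(
    left = lung_chamber(0.05, parabolic_resistor(k_tot, A), k_fs = 0,
                        volume = 0.3335),
    right = lung_chamber(0.05, parabolic_resistor(k_tot, A), k_fs = 0),
    gas = gas, circuit = circuit_loss_model(k_fs = 0, k_cct = 0, area = A))
  tr <- simulate_expiration(sys, 2, dt = 1e-3)
  rms <- sqrt(mean((tr$q_left_lps - cf$flow(tr$time_s))^2))
  expect_lt(rms / cf$peak_flow_lps, 0.005)
  expect_equal(unname(stats::coef(stats::lm(
    q_left_lps ~ time_s, tr[tr$time_s < cf$t_empty * 0.95, ]))[2]),
    -cf$peak_flow_lps / cf$t_empty, tolerance = 1e-3) # linear flow decay
  # scaling laws of the closed form
  cf4 <- single_chamber_emptying(0.05, k_tot, A, gas, 4 * 0.3335)
  expect_equal(cf4$t_empty, 2 * cf$t_empty)
  dense <- gas_mixture(c(He = 0.78, O2 = 0.22), pressure = 4 * 101325)
  expect_equal(single_chamber_emptying(0.05, k_tot, A, dense, 0.3335)$t_empty,
               2 * cf$t_empty, tolerance = 1e-12)
})

test_that("steady-cycle breaths conserve mass and symmetric systems stay symmetric", {
  st <- ventilator_settings(1.0, 20)
  sim <- simulate_lung(make_test_system(k_right = 3.3, gas = medical_air()),
                       st, n_breaths = 4, dt = 1e-3)
  expect_true(sim$steady)
  tr <- sim$trace[sim$trace$breath == 4, ]
  insp <- tr[tr$phase == "inspiration", ]
  ex <- tr[tr$phase == "expiration", ]
  trap <- function(t, q) sum(diff(t) * (q[-1] + q[-length(q)]) / 2)
  v_in <- trap(insp$time_s, insp$q_total_lps)
  v_out <- trap(ex$time_s, ex$q_total_lps)
  expect_equal(v_out / v_in, 1, tolerance = 5e-3)
  # left/right traces identical throughout
  expect_equal(tr$q_left_lps, tr$q_right_lps, tolerance = 1e-9)
  tc <- breath_time_constants(sim)
  expect_equal(tc$left$tau, tc$right$tau, tolerance = 1e-6)
  # chamber volume change equals integrated branch flow (quadrature check)
  dv <- diff(range(insp$v_left_l))
  expect_equal(dv, trap(insp$time_s, insp$q_left_lps), tolerance = 2e-3)
})
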