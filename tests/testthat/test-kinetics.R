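test_that("the tank-concentration estimation chain reproduces the CIMA feed", {
  rc <- cima_rate_constants()
  # chlorite radical from 10 mM chlorite feed, iodine in excess
  expect_equal(estimate_clo2_radical(10e-3), 2e-3)
  expect_equal(estimate_clo2_radical(5e-3), 1e-3)
  expect_equal(estimate_clo2_radical(0), 0)
  expect_error(estimate_clo2_radical(-1e-3), ">= 0")
  # iodine from 2 mM iodide feed minus chlorite-radical consumption
  i2 <- estimate_i2(2e-3, 2e-3)
  expect_equal(i2, 8.7e-4, tolerance = 5e-3)  # printed value rounds 8.667e-4
  expect_equal(estimate_i2(1, 0), 0.6)
  expect_error(estimate_i2(0, 1e-3), "negative")
  # saturating effective k1
  expect_equal(k1_effective(rc, rc$k1b), rc$k1a / 2)
  expect_equal(k1_effective(rc, 1e6), rc$k1a, tolerance = 1e-6)
  expect_equal(k1_effective(rc, 8.7e-4), 7.09e-3, tolerance = 1e-3)
  # dimensionless parameters
  a_coeff <- dimensionless_a(rc, 1, 2e-3, i2)
  expect_equal(a_coeff, 5.9e3, tolerance = 0.02)
  expect_equal(dimensionless_a(rc, 4e-3, 2e-3, i2), 23.6, tolerance = 0.02)
  expect_equal(dimensionless_b(rc, i2, 2e-3), 1.9, tolerance = 0.05 / 1.9)
  expect_error(dimensionless_a(rc, 1e-3, 0, i2), "> 0")
})

test_that("dimensionless a and b are homogeneous of degree 1 in their feeds", {
  rc <- cima_rate_constants()
  i2 <- estimate_i2(2e-3, 2e-3)
  for (s in c(0.5, 2, 7)) {
    expect_equal(dimensionless_a(rc, s * 3e-3, 2e-3, i2),
                 s * dimensionless_a(rc, 3e-3, 2e-3, i2))
    expect_equal(dimensionless_b(rc, s * i2, 2e-3),
                 s * dimensionless_b(rc, i2, 2e-3))
  }
  expect_equal(dimensionless_a(rc, 0, 2e-3, i2), 0)
})

test_that("estimation summary table carries the full chain", {
  rc <- cima_rate_constants()
  tab <- estimate_dimensionless_params(rc, 10e-3, 2e-3, ma0 = 4e-3)
  expect_setequal(tab$quantity,
                  c("ClO2_radical", "I2", "k1_effective", "a_per_MA0", "b",
                    "a"))
  expect_equal(tab$value[tab$quantity == "a"],
               tab$value[tab$quantity == "a_per_MA0"] * 4e-3)
})

test_that("inflow rate follows the pump program and stays nonnegative", {
  ts <- tank_system(MA_s = 20e-3, q0 = 130, A_flow = 40, T = 10)
  expect_equal(inflow_rate(ts, 0), 130)
  expect_equal(inflow_rate(ts, 10 / 4), 170)
  expect_equal(inflow_rate(ts, 3 * 10 / 4), 90)
  expect_true(all(inflow_rate(ts, seq(0, 50, by = 0.1)) >= 0))
  expect_error(tank_system(MA_s = 20e-3, q0 = 30, A_flow = 40, T = 10),
               "q0")
})

test_that("tank mixing ODE matches the closed form for constant inflow", {
  ts <- tank_system(MA_s = 20e-3, q0 = 130, A_flow = 0, T = 10)
  tg <- seq(0, 20, by = 0.25)
  tr <- tank_ma_trajectory(ts, tg, ma_init = 0)
  qtot <- (130 + 499) / 60                       # mL/min
  closed <- 20e-3 * (130 / 629) * (1 - exp(-qtot * tg / 26))
  expect_equal(tr$ma, closed, tolerance = 1e-10)
  # equilibrium initial condition stays constant
  eq <- 20e-3 * 130 / 629
  tr2 <- tank_ma_trajectory(ts, tg, ma_init = eq)
  expect_equal(tr2$ma, rep(eq, length(tg)), tolerance = 1e-12)
  # zero stock decays toward zero
  ts0 <- tank_system(MA_s = 0, q0 = 130, A_flow = 0, T = 10)
  tr3 <- tank_ma_trajectory(ts0, tg, ma_init = 5e-3)
  expect_true(all(diff(tr3$ma) < 0))
  expect_lt(tr3$ma[length(tg)], 5e-3 * exp(-qtot * 20 / 26) * 1.001)
})

test_that("sinusoidal tank trajectory passes step-halving and lsoda checks", {
  ts <- tank_system(MA_s = 45e-3, q0 = 120, A_flow = 60, T = 5)
  tg <- seq(0, 30, by = 0.5)
  tr_h <- tank_ma_trajectory(ts, tg, h = 0.01)
  tr_h2 <- tank_ma_trajectory(ts, tg, h = 0.005)
  expect_lt(max(abs(tr_h$ma - tr_h2$ma)), 1e-8)
  skip_if_not_installed("deSolve")
  sol <- deSolve::lsoda(
    y = c(ma = tr_h$ma[1]), times = tg,
    func = function(t, y, parms) {
      q1 <- (120 + 60 * sin(2 * pi * t / 5)) / 60
      q2 <- 499 / 60
      list(45e-3 * q1 / 26 - y * (q1 + q2) / 26)
    }, parms = NULL, rtol = 1e-10, atol = 1e-14)
  expect_equal(tr_h$ma, unname(sol[, "ma"]), tolerance = 1e-7)
})

test_that("symmetric modulation design yields symmetric extremes", {
  template <- tank_system(MA_s = 45e-3, q0 = 100, T = 10)
  # zero amplitude reduces to the algebraic inversion of the dilution balance
  d0 <- symmetric_modulation_design(7e-3, 0, template)
  expect_equal(d0$A_flow, 0)
  expect_equal(45e-3 * d0$q0 / (d0$q0 + 499), 7e-3, tolerance = 1e-10)
  # moderate modulation: re-simulated extremes symmetric within 0.5%
  d <- symmetric_modulation_design(7e-3, 2.1e-3, template)
  ex <- turingforce:::tank_longrun_extremes(d)
  expect_equal((ex$max + ex$min) / 2, 7e-3, tolerance = 5e-3)
  expect_equal((ex$max - ex$min) / 2, 2.1e-3, tolerance = 5e-3 * 7 / 2.1)
  # designed pump stays in the working range; residence time 2-3 min
  tau <- 60 * d$V / (d$q0 + d$q2)
  expect_gt(tau, 2)
  expect_lt(tau, 3)
  # tank rectification raises the long-run mean slightly above the basis
  # (the centre of the symmetric modulation)
  expect_gt(ex$mean, (ex$max + ex$min) / 2)
  # infeasible request errors with the achievable range
  expect_error(symmetric_modulation_design(7e-3, 7e-3, template),
               "achiev")
})
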