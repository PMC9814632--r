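test_that("zero fields are a fixed point of the diffusion substeps", {
  cfg <- small_config(24)
  st <- field_state(matrix(0, 64, 64), matrix(0, 64, 64))
  st2 <- pde_step(st, cfg, nsteps = 10, kinetics = FALSE)
  expect_identical(max(abs(st2$u)), 0)
  expect_identical(max(abs(st2$v)), 0)
})

test_that("the homogeneous steady state is a fixed point of the full stepper", {
  cfg <- small_config(24)
  ss <- steady_state(cfg$params)
  st <- field_state(matrix(ss["u"], 64, 64), matrix(ss["v"], 64, 64))
  st2 <- pde_step(st, cfg, nsteps = 1000)
  expect_lt(max(abs(st2$u - ss["u"])), 1e-10)
  expect_lt(max(abs(st2$v - ss["v"])), 1e-10)
})

test_that("diffusion substeps conserve the spatial sum of each field", {
  cfg <- small_config(24)
  set.seed(11)
  st <- field_state(matrix(rnorm(64^2, 2, 1), 64, 64),
                    matrix(rnorm(64^2, 10, 2), 64, 64))
  cur <- st
  for (i in 1:5) {
    nxt <- pde_step(cur, cfg, nsteps = 1, kinetics = FALSE,
                    parity = (i - 1) %% 2)
    expect_equal(sum(nxt$u), sum(cur$u), tolerance = 1e-9)
    expect_equal(sum(nxt$v), sum(cur$v), tolerance = 1e-9)
    cur <- nxt
  }
})

test_that("a single Fourier mode decays by the scheme's analytic factor", {
  cfg <- small_config(24)
  nx <- 64
  dx <- 0.25
  dt <- 1e-3
  lam <- function(m) (2 * cos(2 * pi * m / nx) - 2) / dx^2
  symbol <- function(D, mx, my) {
    b <- dt / 2 * D
    (1 + b * lam(my)) / (1 - b * lam(mx)) *
      (1 + b * lam(mx)) / (1 - b * lam(my))
  }
  x <- (0:(nx - 1)) * dx
  for (mode in list(c(3, 0), c(0, 5), c(4, 7))) {
    f <- outer(x, x, function(xx, yy)
      cos(2 * pi * (mode[1] * xx + mode[2] * yy) / (nx * dx)))
    st <- field_state(1e-3 * f, 1e-3 * f)
    st2 <- pde_step(st, cfg, nsteps = 1, kinetics = FALSE)
    proj_u <- sum(st2$u * f) / sum(f * f) / 1e-3
    proj_v <- sum(st2$v * f) / sum(f * f) / 1e-3
    expect_equal(proj_u, symbol(1, mode[1], mode[2]), tolerance = 1e-2)
    expect_equal(proj_v, symbol(8 * 1.5, mode[1], mode[2]), tolerance = 1e-2)
    # the mode stays pure: off-mode residual at round-off level
    expect_lt(max(abs(st2$u - proj_u * 1e-3 * f)), 1e-12)
  }
})

test_that("initial fields are reproducible noise of the configured scale", {
  cfg <- small_config(25, noise_sd = 0.01, seed = 99)
  st1 <- initialize_fields(cfg)
  st2 <- initialize_fields(cfg)
  expect_identical(st1$u, st2$u)
  expect_identical(st1$v, st2$v)
  expect_lt(abs(mean(st1$u)), 3 * 0.01 / 64)          # CLT bound
  expect_equal(sd(st1$u), 0.01, tolerance = 0.05)
  st0 <- initialize_fields(small_config(25, noise_sd = 0))
  expect_identical(max(abs(st0$u)), 0)
})

test_that("halving dt leaves the settled pattern essentially unchanged", {
  cfg1 <- small_config(25, dt = 1e-3, seed = 5)
  init <- initialize_fields(cfg1)
  final1 <- pde_step(init, cfg1, nsteps = 60000)       # t = 60
  cfg2 <- small_config(25, dt = 5e-4, seed = 5)
  final2 <- pde_step(init, cfg2, nsteps = 120000)
  rel <- sqrt(sum((final1$u - final2$u)^2) / sum(final2$u^2))
  expect_lt(rel, 0.01)
  # and the pattern is real: far from the uniform state
  expect_gt(sd(final1$u), 0.5)
})

test_that("coarse and reference grid spacings agree on state and wavelength", {
  # same physical domain (16 x 16), dx = 0.25 vs the reference 0.125
  run_one <- function(dx, nx) {
    cfg <- simulation_config(ref_params(25),
                             list(protocol_stage(60)), dx = dx,
                             nx = nx, ny = nx, dt = 1e-3, seed = 4)
    run_protocol(cfg)$stages[[1]]$report
  }
  r_coarse <- run_one(0.25, 64)
  r_fine <- run_one(0.125, 128)
  expect_true(is_patterned(r_coarse))
  expect_true(is_patterned(r_fine))
  bw <- 2 * pi / 16
  expect_lt(abs(r_coarse$dominant_k - r_fine$dominant_k), bw + 1e-9)
  # dominant wavelength matches the linear-theory prediction within one bin
  dc <- dispersion_relation(ref_params(25), seq(0, 3, by = 0.005))
  expect_lt(abs(r_coarse$dominant_k - dc$leading_k), bw + 1e-9)
})

test_that("protocol runner keeps state continuous and classifies stages", {
  cfg <- small_config(25, duration = 40, seed = 8, snapshot_interval = 10)
  res <- run_protocol(cfg)
  expect_s3_class(res, "protocol_result")
  expect_length(res$stages, 1L)
  expect_equal(res$final$t, 40, tolerance = 1e-9)
  expect_s3_class(res$stages[[1]]$report, "pattern_report")
  ts <- vapply(res$snapshots, function(s) s$t, numeric(1))
  expect_true(all(diff(ts) > 0))
  # restarting from the final state continues the same pattern
  res2 <- run_protocol(small_config(25, duration = 10, seed = 8),
                       init = res$final)
  expect_equal(res2$final$t, 50, tolerance = 1e-9)
})

test_that("field blow-up is reported with the failure time", {
  cfg <- small_config(25, dt = 5)   # far outside the Heun stability regime
  st <- initialize_fields(cfg)
  expect_error(pde_step(st, cfg, nsteps = 2000), "blew up.*time")
})
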