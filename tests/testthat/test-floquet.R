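test_that("unforced orbit below the Hopf point collapses to the steady state", {
  p <- ref_params(22)
  orb <- compute_periodic_orbit(p, le_forcing(A = 0, T = 1), N = 1000)
  ss <- steady_state(p)
  expect_lt(orb$convergence_residual, 1e-6)
  expect_lt(max(abs(orb$u_p - ss["u"])), 1e-5)
  expect_lt(max(abs(orb$v_p - ss["v"])), 1e-4)
})

test_that("forced orbit at the reference point genuinely oscillates", {
  orb <- compute_periodic_orbit(ref_params(22), le_forcing(A = 6, T = 1),
                                N = 10000)
  expect_gt(diff(range(orb$u_p)), 0.1)
  expect_equal(orb$u_p[1], orb$u_p[orb$N + 1], tolerance = 1e-5)
  expect_equal(orb$v_p[1], orb$v_p[orb$N + 1], tolerance = 1e-5)
})

test_that("Euler orbit converges at first order in the step size", {
  p <- ref_params(22)
  f <- le_forcing(A = 6, T = 1)
  ref <- compute_periodic_orbit(p, f, N = 80000)
  err <- vapply(c(2000, 4000), function(N) {
    orb <- compute_periodic_orbit(p, f, N = N)
    idx_ref <- seq(1, 80000 + 1, by = 80000 / N)
    max(abs(orb$u_p - ref$u_p[idx_ref]))
  }, numeric(1))
  expect_equal(err[1] / err[2], 2, tolerance = 0.25)
})

test_that("L(t; k) reduces to the Jacobian at k = 0 and matches finite
           differences of the perturbation dynamics", {
  p <- ref_params(22)
  expect_equal(linearization_matrix(3.1, 12.4, p, 0),
               le_jacobian(3.1, 12.4, p))
  # entries = numerical differentiation of the kinetics plus the analytic
  # diffusion damping of a wavenumber-k mode
  k <- 1.2
  L <- linearization_matrix(3.1, 12.4, p, k)
  expect_equal(L, fd_jacobian(3.1, 12.4, p) -
                 diag(c(k^2, p$sigma * p$c * k^2)), tolerance = 1e-6)
  # large-k asymptotics: diagonal dominated by the diffusion terms
  L_big <- linearization_matrix(3.1, 12.4, p, 50)
  expect_equal(L_big[1, 1], -50^2, tolerance = 1e-2)
  expect_equal(L_big[2, 2], -p$sigma * p$c * 50^2, tolerance = 1e-2)
})

test_that("Poincare product equals direct Euler evolution of a perturbation", {
  orb <- compute_periodic_orbit(ref_params(22), le_forcing(A = 6, T = 1),
                                N = 1000)
  for (k in c(0, 0.7, 1.3)) {
    P <- poincare_map(orb, k)
    for (w0 in list(c(1, 0), c(0, 1), c(0.3, -2))) {
      expect_equal(as.vector(P %*% w0), euler_perturbation(orb, k, w0[1], w0[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("frozen-coefficient product is the matrix power (I + dt L)^N", {
  p <- ref_params(22)
  orb <- compute_periodic_orbit(p, le_forcing(A = 0, T = 1), N = 500)
  k <- 0.8
  ss <- steady_state(p)
  F <- diag(2) + orb$dt * linearization_matrix(ss["u"], ss["v"], p, k)
  Pow <- diag(2)
  for (i in seq_len(orb$N)) Pow <- F %*% Pow
  expect_equal(poincare_map(orb, k), Pow, tolerance = 1e-8)
})

test_that("at A = 0 the multiplier moduli match the dispersion relation", {
  p <- ref_params(22)
  orb <- compute_periodic_orbit(p, le_forcing(A = 0, T = 1), N = 10000)
  ss <- steady_state(p)
  for (k in seq(0, 1, by = 0.1)) {
    P <- poincare_map(orb, k)
    mod_P <- sort(Mod(eigen(P, only.values = TRUE)$values))
    M <- linearization_matrix(ss["u"], ss["v"], p, k)
    mod_exp <- sort(exp(Re(eigen(M, only.values = TRUE)$values)))
    expect_equal(mod_P, mod_exp, tolerance = 1e-2)
  }
})

test_that("det P(k) obeys Liouville's formula", {
  p <- ref_params(22)
  orb <- compute_periodic_orbit(p, le_forcing(A = 6, T = 1), N = 1000000)
  for (k in c(0, 0.6, 1.2)) {
    m <- stability_spectrum(orb, k_grid = c(k, k + 1))
    expect_equal(m$det_P[[1]], exp(orbit_trace_integral(orb, k)),
                 tolerance = 1e-3)
  }
})

test_that("forced state at the reference point destabilizes near k = 1.1", {
  orb <- compute_periodic_orbit(ref_params(22), le_forcing(A = 6, T = 1),
                                N = 10000)
  sp <- stability_spectrum(orb, seq(0, 3, by = 0.01))
  expect_true(any(sp$unstable))
  expect_gt(sp$k_max, 1.0)
  expect_lt(sp$k_max, 1.3)
  # moduli pair with the determinant: |l1 l2| = |det P|
  expect_equal(sp$lambda1_abs * sp$lambda2_abs, abs(sp$det_P),
               tolerance = 1e-10)
  # strong diffusive damping at the top of the grid
  expect_lt(sp$lambda_max[length(sp$k_values)], 1)
  # unforced state at a = 22 is stable at every wavenumber (marginal band)
  orb0 <- compute_periodic_orbit(ref_params(22), le_forcing(A = 0, T = 1),
                                 N = 10000)
  sp0 <- stability_spectrum(orb0, seq(0, 3, by = 0.01))
  expect_lt(max(sp0$lambda_max), 1 + 1e-3)
})

test_that("multiplier moduli are converged in N at the reference point", {
  p <- ref_params(22)
  f <- le_forcing(A = 6, T = 1)
  kg <- seq(0, 2, by = 0.05)
  sp1 <- stability_spectrum(compute_periodic_orbit(p, f, N = 10000), kg)
  sp2 <- stability_spectrum(compute_periodic_orbit(p, f, N = 20000), kg)
  keep <- sp1$lambda_max > 1e-6   # relative change meaningful away from 0
  rel <- abs(sp2$lambda_max[keep] / sp1$lambda_max[keep] - 1)
  expect_lt(max(rel), 5e-3)
})

test_that("T-A phase diagram marks forced instability and unforced stability", {
  p <- ref_params(22)
  pd <- phase_diagram(p, T_values = c(0.5, 1), A_values = c(0, 6),
                      k_grid = seq(0, 2, by = 0.02), N = 4000)
  expect_identical(dim(pd$stability), c(2L, 2L))
  # A = 0 column: uniform state below both bifurcation points is stable
  expect_true(all(pd$stability[, 1]))
  # the reference forced cell (T = 1, A = 6) is unstable
  expect_false(pd$stability[2, 2])
  # refinement self-consistency: halving the k step preserves the diagram
  pd2 <- phase_diagram(p, T_values = c(0.5, 1), A_values = c(0, 6),
                       k_grid = seq(0, 2, by = 0.01), N = 4000)
  expect_identical(pd$stability, pd2$stability)
})
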