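# Shared parameter sets and independent numerical oracles used across tests.

# reference parameter set of the study: sigma = 8, b = 1.9, c = 1.5
ref_params <- function(a) le_params(a = a, b = 1.9, sigma = 8, c = 1.5)

# central finite-difference Jacobian of the unforced reaction terms
fd_jacobian <- function(u, v, params, h = 1e-6) {
  f <- function(uu, vv) {
    r <- reaction_terms(uu, vv, params)
    c(r$du, r$dv)
  }
  unname(cbind((f(u + h, v) - f(u - h, v)) / (2 * h),
               (f(u, v + h) - f(u, v - h)) / (2 * h)))
}

# eigenvalue-based growth rate (base eigen() as the independent route)
eigen_growth <- function(params, k) {
  ss <- steady_state(params)
  J <- le_jacobian(ss["u"], ss["v"], params)
  M <- J - diag(c(k^2, params$sigma * params$c * k^2))
  max(Re(eigen(M, only.values = TRUE)$values))
}

# direct Euler integration of a wavenumber-k perturbation along an orbit;
# algebraically identical to applying the Poincare product to (du0, dv0)
euler_perturbation <- function(orbit, k, du0, dv0) {
  p <- orbit$params
  w <- c(du0, dv0)
  for (i in seq_len(orbit$N)) {
    L <- linearization_matrix(orbit$u_p[i], orbit$v_p[i], p, k)
    w <- w + orbit$dt * (L %*% w)
  }
  as.vector(w)
}

# trace of L(t; k) summed along the orbit (left Riemann quadrature)
orbit_trace_integral <- function(orbit, k) {
  p <- orbit$params
  u <- orbit$u_p[seq_len(orbit$N)]
  v <- orbit$v_p[seq_len(orbit$N)]
  s <- 1 + u^2
  tr <- (-1 + 4 * v * (u^2 - 1) / s^2 - k^2) +
    (-p$sigma * (p$b * u / s + p$c * k^2))
  sum(tr) * orbit$dt
}

# small scaled-down configuration for solver tests (domain 16 x 16)
small_config <- function(a, duration = 60, dt = 1e-3, seed = 1, ...) {
  simulation_config(ref_params(a), list(protocol_stage(duration)),
                    dx = 0.25, nx = 64, ny = 64, dt = dt, seed = seed, ...)
}
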