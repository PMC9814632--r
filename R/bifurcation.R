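#' Dispersion relation of the unforced model
#'
#' Linearizes the unforced model about its homogeneous steady state and, for
#' each wavenumber `k`, records the largest real part among the temporal
#' eigenvalues of `M(k) = J - diag(k^2, sigma * c * k^2)`, where `J` is the
#' kinetics Jacobian at the steady state.  The inhibitor diffuses with
#' coefficient `sigma * c` because the whole second equation carries the
#' factor `sigma`.
#'
#' @param params An [le_params] object.
#' @param k_grid Nonnegative, strictly increasing wavenumbers starting at 0.
#' @return An object of class `dispersion_curve`: list with `k_values`,
#'   `growth_rates` and `leading_k` (the argmax wavenumber).
#' @examples
#' dc <- dispersion_relation(le_params(a = 24), seq(0, 3, by = 0.01))
#' dc$leading_k
#' @export
dispersion_relation <- function(params, k_grid = seq(0, 3, by = 0.01)) {
  stopifnot(inherits(params, "le_params"), is.numeric(k_grid))
  if (any(k_grid < 0) || any(diff(k_grid) <= 0))
    stop("'k_grid' must be nonnegative and strictly increasing")
  ss <- steady_state(params)
  J <- le_jacobian(ss["u"], ss["v"], params)
  growth <- vapply(k_grid, function(k)
    growth_rate_at_k(J, k, params$sigma * params$c), numeric(1))
  structure(list(k_values = k_grid, growth_rates = growth,
                 leading_k = k_grid[which.max(growth)],
                 params = params),
            class = "dispersion_curve")
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf(paste0("Dispersion curve over k in [%g, %g] (%d points): ",
                     "max growth %.4g at k = %.3g\n"),
              min(x$k_values), max(x$k_values), length(x$k_values),
              max(x$growth_rates), x$leading_k))
  invisible(x)
}

# largest real eigenvalue part of J - diag(k^2, dv * k^2), via the
# characteristic polynomial of the 2x2 matrix
growth_rate_at_k <- function(J, k, dv) {
  m11 <- J[1, 1] - k^2
  m22 <- J[2, 2] - dv * k^2
  tr <- m11 + m22
  det <- m11 * m22 - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
}

# maximal growth over k > 0: coarse scan plus local refinement
max_growth_over_k <- function(params, k_max = 5) {
  ss <- steady_state(params)
  J <- le_jacobian(ss["u"], ss["v"], params)
  dv <- params$sigma * params$c
  ks <- seq(1e-3, k_max, length.out = 400L)
  g <- vapply(ks, function(k) growth_rate_at_k(J, k, dv), numeric(1))
  i <- which.max(g)
  lo <- ks[max(1L, i - 1L)]
  hi <- ks[min(length(ks), i + 1L)]
  opt <- stats::optimize(function(k) growth_rate_at_k(J, k, dv),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  list(growth = opt$objective, k = opt$maximum)
}

#' Hopf bifurcation point in a
#'
#' Critical feed parameter at which the homogeneous steady state loses
#' stability to temporal oscillations: the root in `a` of the trace of the
#' kinetics Jacobian at the steady state, with the determinant required to be
#' positive there (a genuine Hopf point).
#'
#' @param sigma,b,c Fixed model parameters.
#' @param interval Bracketing interval in `a` searched for the sign change.
#' @return Critical value of `a` (to better than 1e-4).
#' @export
hopf_point <- function(sigma = 8, b = 1.9, c = 1.5, interval = c(1, 200)) {
  trace_at <- function(a) {
    p <- le_params(a = a, b = b, sigma = sigma, c = c)
    ss <- steady_state(p)
    J <- le_jacobian(ss["u"], ss["v"], p)
    J[1, 1] + J[2, 2]
  }
  f_lo <- trace_at(interval[1])
  f_hi <- trace_at(interval[2])
  if (sign(f_lo) == sign(f_hi))
    stop("no sign change of the Jacobian trace in the bracketing interval")
  root <- stats::uniroot(trace_at, interval = interval, tol = 1e-8)$root
  p <- le_params(a = root, b = b, sigma = sigma, c = c)
  ss <- steady_state(p)
  J <- le_jacobian(ss["u"], ss["v"], p)
  if (det(J) <= 0)
    stop("trace root found but determinant is not positive (not a Hopf point)")
  root
}

#' Turing bifurcation point in a
#'
#' Smallest `a` at which the maximal growth rate of the dispersion relation
#' over `k > 0` crosses zero while the homogeneous (`k = 0`) mode remains
#' stable: the onset of the diffusion-driven instability.  Located by
#' bisection in `a` on the maximal growth (itself found by scan plus local
#' refinement over `k` in `(0, k_max]`).
#'
#' @param sigma,b,c Fixed model parameters.
#' @param a_min Lower end of the interval in `a` scanned for the marginal
#'   point (the upper end is the Hopf point, keeping `k = 0` stable).
#' @param k_max Upper end of the wavenumber search range.
#' @return List with `a` (critical value, to better than 1e-4) and `k_c`
#'   (marginal wavenumber).
#' @export
turing_point <- function(sigma = 8, b = 1.9, c = 1.5,
                         a_min = 5, k_max = 5) {
  a_hopf <- hopf_point(sigma = sigma, b = b, c = c)
  lo <- a_min
  hi <- a_hopf - 1e-3  # require k = 0 stable
  gmax <- function(a)
    max_growth_over_k(le_params(a = a, b = b, sigma = sigma, c = c),
                      k_max = k_max)$growth
  g_lo <- gmax(lo)
  g_hi <- gmax(hi)
  if (g_lo >= 0)
    stop(sprintf("maximal growth already positive at a = %g; widen interval",
                 lo))
  if (g_hi <= 0)
    stop(sprintf(paste0("no Turing instability found for a in [%g, %g] ",
                        "(k in (0, %g])"), lo, hi, k_max))
  root <- stats::uniroot(gmax, interval = c(lo, hi), tol = 1e-8)$root
  kc <- max_growth_over_k(le_params(a = root, b = b, sigma = sigma, c = c),
                          k_max = k_max)$k
  list(a = root, k_c = kc)
}
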