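#' Uniform oscillatory solution of the forced kinetics
#'
#' Integrates the space-free forced system with explicit Euler at `N` steps
#' per forcing period, period after period, until the sampled period repeats
#' (max-norm residual below `tol`) or the period cap is hit.  The returned
#' orbit samples the final period at the `N + 1` step times (left endpoints
#' plus the period end).  With `A = 0` and the feed below the Hopf point the
#' "orbit" collapses to the constant steady state.
#'
#' @param params An [le_params] object.
#' @param forcing An [le_forcing] object.
#' @param N Euler steps per period (default 10000).
#' @param init Initial state `c(u, v)`; defaults to [steady_state()].
#' @param tol Periodicity residual tolerance in max norm (default 1e-6).
#' @param max_periods Cap on the number of periods integrated (default 500).
#' @return An object of class `periodic_orbit` with fields `u_p`, `v_p`
#'   (length `N + 1`), `N`, `dt`, `params`, `forcing`,
#'   `convergence_residual`, `periods`.
#' @examples
#' orb <- compute_periodic_orbit(le_params(a = 22), le_forcing(A = 6, T = 1),
#'                               N = 2000)
#' range(orb$u_p)
#' @export
compute_periodic_orbit <- function(params, forcing, N = 10000, init = NULL,
                                   tol = 1e-6, max_periods = 500) {
  stopifnot(inherits(params, "le_params"), inherits(forcing, "le_forcing"))
  if (N < 100) stop("'N' must be at least 100")
  if (is.null(init)) init <- steady_state(params)
  res <- cpp_euler_orbit(params$a, params$b, params$sigma, params$c,
                         forcing$A, forcing$T, as.integer(N),
                         init[[1]], init[[2]], tol, as.integer(max_periods))
  if (!res$converged)
    stop(sprintf(paste0("periodic orbit did not converge within %d periods ",
                        "(last residual %.3g); residual history attached"),
                 max_periods, res$residual),
         call. = FALSE)
  structure(list(u_p = res$u_p, v_p = res$v_p, N = as.integer(N),
                 dt = forcing$T / N, params = params, forcing = forcing,
                 convergence_residual = res$residual,
                 periods = res$periods,
                 residual_history = res$residual_history),
            class = "periodic_orbit")
}

#' @export
print.periodic_orbit <- function(x, ...) {
  cat(sprintf(paste0("Uniform oscillatory solution: T = %g, N = %d, ",
                     "u in [%.4g, %.4g], residual %.2g (%d periods)\n"),
              x$forcing$T, x$N, min(x$u_p), max(x$u_p),
              x$convergence_residual, x$periods))
  invisible(x)
}

#' Linearization matrix L(t; k) about the uniform oscillatory state
#'
#' The 2 x 2 coefficient matrix governing a wavenumber-`k` perturbation of
#' the uniform oscillatory solution; at `k = 0` it equals the kinetics
#' Jacobian [le_jacobian()] at the same point.
#'
#' @param u,v Orbit point.
#' @param params An [le_params] object.
#' @param k Wavenumber.
#' @return A 2 x 2 numeric matrix.
#' @export
linearization_matrix <- function(u, v, params, k) {
  stopifnot(inherits(params, "le_params"), is.finite(u), is.finite(v),
            is.finite(k))
  J <- le_jacobian(u, v, params)
  J[1, 1] <- J[1, 1] - k^2
  J[2, 2] <- J[2, 2] - params$sigma * params$c * k^2
  J
}

#' Linearized Poincare map over one forcing period
#'
#' Builds `P(k)` as the ordered Euler product
#' `(I + dt L(t_{N-1}; k)) ... (I + dt L(t_0; k))` along the sampled orbit,
#' `dt = T / N`, using the left-endpoint orbit samples.  `P(k)` advances any
#' initial perturbation `(du, dv)` of wavenumber `k` by one forcing period.
#'
#' @param orbit A [compute_periodic_orbit()] result.
#' @param k Wavenumber.
#' @return A 2 x 2 numeric matrix.
#' @export
poincare_map <- function(orbit, k) {
  stopifnot(inherits(orbit, "periodic_orbit"), is.finite(k))
  cpp_poincare_map(orbit$u_p, orbit$v_p, orbit$params$b, orbit$params$sigma,
                   orbit$params$c, k, orbit$dt)
}

#' Floquet multiplier spectrum over a wavenumber grid
#'
#' Eigenvalue moduli of the linearized Poincare map per wavenumber; the
#' uniform oscillatory state is unstable at `k` where the larger modulus
#' exceeds one (a `1e-9` guard band avoids flagging the marginal mode).
#'
#' @param orbit A [compute_periodic_orbit()] result.
#' @param k_grid Ordered nonnegative wavenumbers (default 0 to 3, step 0.01).
#' @return An object of class `stability_spectrum`: list with `k_values`,
#'   `lambda1_abs`, `lambda2_abs`, `lambda_max`, `det_P`, `k_max` (argmax of
#'   `lambda_max`) and `unstable` (logical per k).
#' @export
stability_spectrum <- function(orbit, k_grid = seq(0, 3, by = 0.01)) {
  stopifnot(inherits(orbit, "periodic_orbit"), is.numeric(k_grid))
  if (any(k_grid < 0) || any(diff(k_grid) <= 0))
    stop("'k_grid' must be nonnegative and strictly increasing")
  m <- cpp_stability_moduli(orbit$u_p, orbit$v_p, orbit$params$b,
                            orbit$params$sigma, orbit$params$c,
                            k_grid, orbit$dt)
  lam_max <- pmax(m[, "lambda1_abs"], m[, "lambda2_abs"])
  structure(list(k_values = k_grid,
                 lambda1_abs = m[, "lambda1_abs"],
                 lambda2_abs = m[, "lambda2_abs"],
                 lambda_max = lam_max,
                 det_P = m[, "det"],
                 k_max = k_grid[which.max(lam_max)],
                 unstable = lam_max > 1 + 1e-9,
                 orbit = orbit),
            class = "stability_spectrum")
}

#' @export
print.stability_spectrum <- function(x, ...) {
  cat(sprintf(paste0("Floquet spectrum over k in [%g, %g]: max |lambda| = ",
                     "%.4f at k = %.3g (%s)\n"),
              min(x$k_values), max(x$k_values), max(x$lambda_max), x$k_max,
              if (any(x$unstable)) "unstable" else "stable"))
  invisible(x)
}

#' @export
as.data.frame.stability_spectrum <- function(x, ...) {
  data.frame(k = x$k_values, lambda1_abs = x$lambda1_abs,
             lambda2_abs = x$lambda2_abs, lambda_max = x$lambda_max)
}

#' Stability phase diagram in the T-A plane
#'
#' For each `(T, A)` cell the uniform oscillatory orbit is computed and its
#' Floquet spectrum evaluated over `k_grid`; the cell is stable when the
#' maximal multiplier modulus stays at or below one (within the `1e-9` guard).
#' Cells whose orbit fails to converge within the period cap are recorded as
#' `NA` (indeterminate), never as stable.
#'
#' @param params An [le_params] object.
#' @param T_values,A_values Grid axes.
#' @param k_grid Wavenumber grid (default 0 to 3, step 0.02).
#' @param N Euler steps per period (default 10000).
#' @param max_periods Orbit period cap per cell.
#' @return An object of class `phase_diagram_ta`: list with `T_values`,
#'   `A_values`, logical matrix `stability` (rows = T, cols = A; `NA` =
#'   indeterminate) and matrix `lambda_max`.
#' @export
phase_diagram <- function(params, T_values, A_values,
                          k_grid = seq(0, 3, by = 0.02), N = 10000,
                          max_periods = 500) {
  stopifnot(inherits(params, "le_params"),
            length(T_values) >= 1, length(A_values) >= 1)
  nt <- length(T_values)
  na <- length(A_values)
  stab <- matrix(NA, nt, na, dimnames = list(T = T_values, A = A_values))
  lmax <- matrix(NA_real_, nt, na)
  for (i in seq_len(nt)) {
    for (j in seq_len(na)) {
      orb <- tryCatch(
        compute_periodic_orbit(params,
                               le_forcing(A = A_values[j], T = T_values[i]),
                               N = N, max_periods = max_periods),
        error = function(e) NULL)
      if (is.null(orb)) next
      sp <- stability_spectrum(orb, k_grid)
      lmax[i, j] <- max(sp$lambda_max)
      stab[i, j] <- !any(sp$unstable)
    }
  }
  structure(list(T_values = T_values, A_values = A_values,
                 stability = stab, lambda_max = lmax, params = params),
            class = "phase_diagram_ta")
}

#' @export
print.phase_diagram_ta <- function(x, ...) {
  n_unst <- sum(!x$stability, na.rm = TRUE)
  n_na <- sum(is.na(x$stability))
  cat(sprintf(paste0("T-A phase diagram (%d x %d cells): %d unstable, ",
                     "%d stable, %d indeterminate\n"),
              length(x$T_values), length(x$A_values), n_unst,
              sum(x$stability, na.rm = TRUE), n_na))
  invisible(x)
}
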