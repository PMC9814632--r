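#' CIMA rate constants
#'
#' Rate constants of the skeleton CIMA mechanism used to map dimensional feed
#' concentrations onto the dimensionless model parameters.  Defaults are the
#' literature values for the chlorite-iodide-malonic acid system at the
#' conditions of a two-sided-fed gel reactor experiment: `k1a` (1/s) and `k1b`
#' (M) parameterize the saturating MA + I2 rate, `k2` (1/(M s)) the
#' ClO2-radical + iodide step, `k3` (1/s) the chlorite-iodide-MA step with
#' kinetic parameter `alpha` (M^2).  `K` is the triiodide-complex equilibrium
#' constant (so `sigma = 1 + K`), and `D_X`, `D_Y` the diffusion coefficients
#' of activator and inhibitor in consistent units (only their ratio matters).
#'
#' @param k1a,k1b,k2,k3,alpha,K,D_X,D_Y Strictly positive numerics, see above.
#' @return An object of class `cima_rates`.
#' @export
cima_rate_constants <- function(k1a = 7.5e-3, k1b = 5e-5, k2 = 6e3,
                                k3 = 2.65e-3, alpha = 1e-14,
                                K = 7, D_X = 1, D_Y = 1.5) {
  vals <- c(k1a = k1a, k1b = k1b, k2 = k2, k3 = k3, alpha = alpha,
            K = K, D_X = D_X, D_Y = D_Y)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all rate constants must be strictly positive and finite")
  structure(as.list(vals), class = "cima_rates")
}

#' Estimate the chlorite-radical concentration in the tank
#'
#' With iodine in excess the rapid chlorite-iodine equilibrium gives
#' `[ClO2.] = 0.2 [ClO2^-]`.
#'
#' @param clo2_anion Chlorite feed concentration in M; nonnegative.
#' @return Estimated ClO2 radical concentration in M.
#' @export
estimate_clo2_radical <- function(clo2_anion) {
  stopifnot(is.numeric(clo2_anion))
  if (any(clo2_anion < 0)) stop("chlorite concentration must be >= 0")
  0.2 * clo2_anion
}

#' Estimate the iodine concentration in the tank
#'
#' Iodine forms from iodide via the Dushman stoichiometry (3/5 of the iodide
#' feed with iodate in excess) and is partly consumed by the chlorite-iodine
#' reaction (1/6 of the ClO2 radical concentration):
#' `[I2] = (3/5) [I^-] - (1/6) [ClO2.]`.
#'
#' @param iodide Iodide feed concentration in M.
#' @param clo2_rad ClO2 radical concentration in M.
#' @return Estimated I2 concentration in M.  A negative balance signals an
#'   inconsistent feed composition and raises an error.
#' @export
estimate_i2 <- function(iodide, clo2_rad) {
  stopifnot(is.numeric(iodide), is.numeric(clo2_rad))
  if (any(iodide < 0) || any(clo2_rad < 0)) stop("concentrations must be >= 0")
  i2 <- (3 / 5) * iodide - (1 / 6) * clo2_rad
  if (any(i2 < 0))
    stop("inconsistent feed composition: estimated [I2] would be negative")
  i2
}

#' Effective first-order rate constant k1
#'
#' Saturating dependence of the MA iodination rate on iodine:
#' `k1 = k1a * [I2] / (k1b + [I2])`; monotone in `[I2]`, bounded by `k1a`.
#'
#' @param rc A [cima_rate_constants] object.
#' @param i2 Iodine concentration in M; nonnegative.
#' @return Effective rate constant in 1/s.
#' @export
k1_effective <- function(rc, i2) {
  stopifnot(inherits(rc, "cima_rates"), is.numeric(i2))
  if (any(i2 < 0)) stop("[I2] must be >= 0")
  rc$k1a * i2 / (rc$k1b + i2)
}

#' Dimensionless feed parameter a from tank concentrations
#'
#' `a = k1 [MA]0 / (k2 [ClO2.]0 sqrt(alpha))`, linear in the malonic acid feed
#' concentration.
#'
#' @param rc A [cima_rate_constants] object.
#' @param ma0 Malonic acid feed concentration in M.
#' @param clo2_rad ClO2 radical concentration in M; strictly positive.
#' @param i2 Iodine concentration in M.
#' @return Dimensionless parameter `a`.
#' @export
dimensionless_a <- function(rc, ma0, clo2_rad, i2) {
  stopifnot(inherits(rc, "cima_rates"), is.numeric(ma0))
  if (any(clo2_rad <= 0)) stop("[ClO2.] must be > 0")
  if (any(ma0 < 0)) stop("[MA]0 must be >= 0")
  k1_effective(rc, i2) * ma0 / (rc$k2 * clo2_rad * sqrt(rc$alpha))
}

#' Dimensionless feed parameter b from tank concentrations
#'
#' `b = k3 [I2]0 / (k2 [ClO2.]0 sqrt(alpha))`, linear in the iodine
#' concentration.
#'
#' @inheritParams dimensionless_a
#' @return Dimensionless parameter `b`.
#' @export
dimensionless_b <- function(rc, i2, clo2_rad) {
  stopifnot(inherits(rc, "cima_rates"), is.numeric(i2))
  if (any(clo2_rad <= 0)) stop("[ClO2.] must be > 0")
  if (any(i2 < 0)) stop("[I2] must be >= 0")
  rc$k3 * i2 / (rc$k2 * clo2_rad * sqrt(rc$alpha))
}

#' Full parameter-estimation chain from feed concentrations
#'
#' Convenience wrapper running the whole estimation: chlorite radical from the
#' chlorite feed, iodine from the iodide feed, effective `k1`, the coefficient
#' `a / [MA]0` (in 1/M), and `b`.
#'
#' @param rc A [cima_rate_constants] object.
#' @param clo2_anion Chlorite feed concentration in M.
#' @param iodide Iodide feed concentration in M.
#' @param ma0 Optional malonic acid feed concentration in M; if supplied the
#'   resulting `a` is included.
#' @return A data.frame with one row per quantity (`quantity`, `value`,
#'   `units`).
#' @examples
#' rc <- cima_rate_constants()
#' estimate_dimensionless_params(rc, clo2_anion = 10e-3, iodide = 2e-3,
#'                               ma0 = 4e-3)
#' @export
estimate_dimensionless_params <- function(rc, clo2_anion, iodide, ma0 = NULL) {
  clo2_rad <- estimate_clo2_radical(clo2_anion)
  i2 <- estimate_i2(iodide, clo2_rad)
  k1 <- k1_effective(rc, i2)
  a_coeff <- dimensionless_a(rc, 1, clo2_rad, i2)
  b <- dimensionless_b(rc, i2, clo2_rad)
  out <- data.frame(
    quantity = c("ClO2_radical", "I2", "k1_effective", "a_per_MA0", "b"),
    value = c(clo2_rad, i2, k1, a_coeff, b),
    units = c("M", "M", "1/s", "1/M", "dimensionless"),
    stringsAsFactors = FALSE)
  if (!is.null(ma0)) {
    out <- rbind(out, data.frame(quantity = "a", value = a_coeff * ma0,
                                 units = "dimensionless"))
  }
  out
}

#' Stirred-tank feed system
#'
#' Parameters of the continuously stirred tank whose malonic acid feed is
#' modulated: `MA_s` is the MA concentration of the modulated stock solution
#' (M), `V` the tank volume (mL), `q0` the base inflow rate of the modulated
#' pump (mL/h), `q2` the constant co-feed rate (mL/h), `A_flow` the flow
#' modulation amplitude (mL/h) and `T` the modulation period (min).
#'
#' @param MA_s,V,q0,q2,A_flow,T See above.
#' @return An object of class `tank_system`.
#' @export
tank_system <- function(MA_s, V = 26, q0, q2 = 499, A_flow = 0, T = 10) {
  vals <- c(MA_s = MA_s, V = V, q0 = q0, q2 = q2, A_flow = A_flow, T = T)
  if (!all(is.finite(vals))) stop("tank parameters must be finite")
  if (V <= 0) stop("'V' must be > 0")
  if (q2 <= 0) stop("'q2' must be > 0")
  if (A_flow < 0) stop("'A_flow' must be >= 0")
  if (q0 < A_flow) stop("'q0' must be >= 'A_flow' (inflow cannot go negative)")
  if (T <= 0) stop("'T' must be > 0")
  if (MA_s < 0) stop("'MA_s' must be >= 0")
  structure(as.list(vals), class = "tank_system")
}

#' @export
print.tank_system <- function(x, ...) {
  cat(sprintf(paste0("Stirred-tank feed: [MA]_s = %g M, V = %g mL, ",
                     "q0 = %g mL/h, q2 = %g mL/h, A = %g mL/h, T = %g min\n"),
              x$MA_s, x$V, x$q0, x$q2, x$A_flow, x$T))
  cat(sprintf("  residence time V/(q0+q2) = %.2f min\n",
              60 * x$V / (x$q0 + x$q2)))
  invisible(x)
}

#' Instantaneous inflow rate of the modulated pump
#'
#' `q1(t) = q0 + A_flow * sin(2 pi t / T)`; never negative because
#' `q0 >= A_flow` is enforced at construction.
#'
#' @param ts A [tank_system] object.
#' @param t Time(s) in minutes.
#' @return Inflow rate(s) in mL/h.
#' @export
inflow_rate <- function(ts, t) {
  stopifnot(inherits(ts, "tank_system"))
  ts$q0 + ts$A_flow * sin(2 * pi * t / ts$T)
}

# d[MA]0/dt in M/min; q in mL/h is converted to mL/min
ma_ode_rhs <- function(ts, t, ma) {
  q1 <- inflow_rate(ts, t) / 60
  q2 <- ts$q2 / 60
  ts$MA_s * q1 / ts$V - ma * (q1 + q2) / ts$V
}

#' Tank malonic acid concentration trajectory
#'
#' Integrates the linear mixing ODE
#' `d[MA]0/dt = [MA]_s q1(t)/V - [MA]0 (q1(t) + q2)/V`
#' with a fixed-step classical fourth-order Runge-Kutta scheme (step 0.01 min,
#' refined to divide the output grid).  With `A_flow = 0` the trajectory
#' relaxes to `[MA]_s q0 / (q0 + q2)`.
#'
#' @param ts A [tank_system] object.
#' @param t_grid Increasing vector of output times in minutes, starting at the
#'   initial time.
#' @param ma_init Initial concentration in M; defaults to the unmodulated
#'   steady value `[MA]_s q1(0) / (q1(0) + q2)`.
#' @param h Integration step in minutes (default 0.01).
#' @return A data.frame with columns `t` (min), `q1` (mL/h) and `ma` (M).
#' @export
tank_ma_trajectory <- function(ts, t_grid, ma_init = NULL, h = 0.01) {
  stopifnot(inherits(ts, "tank_system"), is.numeric(t_grid),
            length(t_grid) >= 2L, all(diff(t_grid) > 0))
  if (is.null(ma_init)) {
    q10 <- inflow_rate(ts, t_grid[1])
    ma_init <- ts$MA_s * q10 / (q10 + ts$q2)
  }
  if (ma_init < 0) stop("'ma_init' must be >= 0")
  ma <- numeric(length(t_grid))
  ma[1] <- ma_init
  y <- ma_init
  for (i in seq_len(length(t_grid) - 1L)) {
    t0 <- t_grid[i]
    t1 <- t_grid[i + 1L]
    nsub <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / nsub
    for (j in seq_len(nsub)) {
      tj <- t0 + (j - 1) * hh
      k1 <- ma_ode_rhs(ts, tj, y)
      k2 <- ma_ode_rhs(ts, tj + hh / 2, y + hh * k1 / 2)
      k3 <- ma_ode_rhs(ts, tj + hh / 2, y + hh * k2 / 2)
      k4 <- ma_ode_rhs(ts, tj + hh, y + hh * k3)
      y <- y + hh * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    ma[i + 1L] <- y
  }
  data.frame(t = t_grid, q1 = inflow_rate(ts, t_grid), ma = ma)
}

# long-run extremes of the periodic [MA]0(t): integrate through the transient
# (several residence times), then measure min/max/mean over one period
tank_longrun_extremes <- function(ts, periods_settle = NULL) {
  tau <- 60 * ts$V / (ts$q0 + ts$q2)           # residence time, min
  settle <- max(10 * tau, 2 * ts$T)
  if (!is.null(periods_settle)) settle <- periods_settle * ts$T
  n_settle <- ceiling(settle / ts$T)
  t_end <- (n_settle + 1) * ts$T
  grid <- seq(0, t_end, by = min(ts$T / 200, 0.05))
  traj <- tank_ma_trajectory(ts, grid)
  last <- traj$t >= n_settle * ts$T
  list(min = min(traj$ma[last]), max = max(traj$ma[last]),
       mean = mean(traj$ma[last]))
}

#' Design a symmetric feed-concentration modulation
#'
#' Finds pump settings `(q0, A_flow)` such that the long-run periodic tank
#' concentration oscillates symmetrically about a requested basis value:
#' the extremes `[MA]0_max` and `[MA]0_min` are equidistant from
#' `target_basis`, with half-range `target_amplitude`.  Because the tank mixing
#' damps and distorts the sinusoid, the settings are found by damped Newton
#' root-finding on the simulated long-run trajectory rather than algebraically.
#'
#' @param target_basis Requested basis concentration in M.
#' @param target_amplitude Requested half-range of the modulation in M
#'   (0 requests a constant feed).
#' @param ts A [tank_system] object supplying `MA_s`, `V`, `q2` and `T`; its
#'   `q0`/`A_flow` are ignored and replaced by the designed values.
#' @param tol Relative tolerance on basis symmetry and amplitude (default
#'   0.5\% of `target_basis`).
#' @return A [tank_system] with the designed `q0` and `A_flow`, carrying the
#'   achieved extremes as attribute `"achieved"`.
#' @export
symmetric_modulation_design <- function(target_basis, target_amplitude, ts,
                                        tol = 5e-3) {
  stopifnot(inherits(ts, "tank_system"),
            target_basis > 0, target_amplitude >= 0)
  if (target_basis >= ts$MA_s)
    stop("'target_basis' must be below the stock concentration 'MA_s'")
  q0 <- ts$q2 * target_basis / (ts$MA_s - target_basis)
  if (target_amplitude == 0) {
    out <- tank_system(MA_s = ts$MA_s, V = ts$V, q0 = q0, q2 = ts$q2,
                       A_flow = 0, T = ts$T)
    attr(out, "achieved") <- list(basis = target_basis, amplitude = 0)
    return(out)
  }
  # initial amplitude guess: quasi-static gain times first-order filter
  dcdq <- ts$MA_s * ts$q2 / (q0 + ts$q2)^2
  tau <- 60 * ts$V / (q0 + ts$q2)
  gain <- 1 / sqrt(1 + (2 * pi * tau / ts$T)^2)
  A <- target_amplitude / (dcdq * gain)
  A <- min(A, 0.95 * q0)
  measure <- function(q0, A) {
    sys <- tank_system(MA_s = ts$MA_s, V = ts$V, q0 = q0, q2 = ts$q2,
                       A_flow = A, T = ts$T)
    ex <- tank_longrun_extremes(sys)
    c(mid = (ex$max + ex$min) / 2, half = (ex$max - ex$min) / 2)
  }
  for (it in 1:40) {
    m <- measure(q0, A)
    res <- c(m["mid"] - target_basis, m["half"] - target_amplitude)
    if (max(abs(res)) < tol * target_basis) break
    # numerical Jacobian of (mid, half) wrt (q0, A)
    dq <- max(1e-3 * q0, 0.1)
    dA <- max(1e-3 * max(A, 1), 0.1)
    mq <- measure(q0 + dq, A)
    mA <- measure(q0, min(A + dA, q0))
    J <- cbind((mq - m) / dq, (mA - m) / dA)
    step <- tryCatch(solve(J, res), error = function(e) res * 0)
    if (all(step == 0)) break
    q0_new <- q0 - step[1]
    A_new <- A - step[2]
    if (!is.finite(q0_new) || !is.finite(A_new) || q0_new <= 0)
      break
    q0 <- q0_new
    A <- max(A_new, 0)
    if (A > q0) {
      A <- q0  # pump cannot run backwards; clamp and let residual report
    }
  }
  m <- measure(q0, A)
  res <- c(m["mid"] - target_basis, m["half"] - target_amplitude)
  if (max(abs(res)) >= tol * target_basis) {
    stop(sprintf(paste0("requested modulation is not achievable with ",
                        "nonnegative inflow; achieved basis %.4g M, ",
                        "amplitude %.4g M (requested %.4g +/- %.4g M)"),
                 m["mid"], m["half"], target_basis, target_amplitude))
  }
  out <- tank_system(MA_s = ts$MA_s, V = ts$V, q0 = q0, q2 = ts$q2,
                     A_flow = A, T = ts$T)
  attr(out, "achieved") <- list(basis = unname(m["mid"]),
                                amplitude = unname(m["half"]))
  out
}
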