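#' Forcing protocol stage
#'
#' One stage of a simulation protocol: integrate for `duration` dimensionless
#' time units under sinusoidal forcing `(A, T)`; `A = 0` gives an unforced
#' stage.  The forcing phase restarts at zero at each stage onset.
#'
#' @param duration Stage length in dimensionless time; positive.
#' @param A,T Forcing amplitude and period for the stage.
#' @return An object of class `protocol_stage`.
#' @export
protocol_stage <- function(duration, A = 0, T = 1) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  structure(list(duration = duration, forcing = le_forcing(A = A, T = T)),
            class = "protocol_stage")
}

#' Simulation configuration
#'
#' Grid, time step, noise and protocol for the 2-D reaction-diffusion
#' simulator.  Defaults reproduce the reference numerics: domain 50 x 50 with
#' grid spacing `dx = dy = 0.125` and time step `dt = 3.124e-4`; initial
#' fields are zero plus Gaussian noise of standard deviation 0.01.
#'
#' @param params An [le_params] object.
#' @param stages List of [protocol_stage] objects (at least one).
#' @param dx Grid spacing (equal in x and y).
#' @param nx,ny Grid points per axis; default `round(50 / dx)`.
#' @param dt Time step.
#' @param noise_sd Standard deviation of the initial Gaussian noise.
#' @param seed RNG seed controlling the single noise draw.
#' @param snapshot_interval Simulated time between saved frames.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params, stages, dx = 0.125,
                              nx = round(50 / dx), ny = nx,
                              dt = 3.124e-4, noise_sd = 0.01, seed = 1,
                              snapshot_interval = 5) {
  stopifnot(inherits(params, "le_params"), is.list(stages),
            length(stages) >= 1L)
  if (!all(vapply(stages, inherits, logical(1), "protocol_stage")))
    stop("'stages' must be a list of protocol_stage objects")
  if (dx <= 0 || dt <= 0) stop("'dx' and 'dt' must be > 0")
  if (nx < 16 || ny < 16) stop("grid must have at least 16 points per axis")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(params = params, stages = stages, nx = as.integer(nx),
                 ny = as.integer(ny), dx = dx, dt = dt,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 snapshot_interval = snapshot_interval),
            class = "simulation_config")
}

#' Scaled-down simulation preset
#'
#' Convenience preset on a 25 x 25 domain with `dx = 0.25` and `dt = 1e-3`;
#' coarser than the reference numerics but, within the scheme's accuracy
#' regime, yielding the same state classifications and dominant wavenumbers.
#'
#' @param a Feed parameter.
#' @param stages List of [protocol_stage] objects; default one unforced stage
#'   of length 300.
#' @param seed RNG seed.
#' @param ... Passed on to [simulation_config()] (e.g. `noise_sd`,
#'   `snapshot_interval`, overrides of `b`, `sigma`, `c` via `params`).
#' @return A `simulation_config`.
#' @export
fast_config <- function(a, stages = list(protocol_stage(300)), seed = 1,
                        ...) {
  simulation_config(le_params(a = a), stages = stages, dx = 0.25,
                    nx = 100, ny = 100, dt = 1e-3, seed = seed, ...)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d x %d grid, dx = %g (domain ",
                     "%g x %g), dt = %g, noise sd = %g, seed = %d\n"),
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx, x$dt,
              x$noise_sd, x$seed))
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cat(sprintf("  stage %d: duration %g, A = %g, T = %g\n", i,
                st$duration, st$forcing$A, st$forcing$T))
  }
  invisible(x)
}

#' Initial fields
#'
#' Both concentration fields start at zero with independent Gaussian noise of
#' standard deviation `noise_sd` added; the draw is reproducible from the
#' configuration seed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `field_state`: list with matrices `u`, `v` and
#'   time `t = 0`.
#' @export
initialize_fields <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$nx * config$ny
  u <- matrix(stats::rnorm(n, 0, config$noise_sd), config$nx, config$ny)
  v <- matrix(stats::rnorm(n, 0, config$noise_sd), config$nx, config$ny)
  field_state(u, v, t = 0)
}

#' Field state container
#'
#' @param u,v Concentration matrices of equal dimension.
#' @param t Time stamp.
#' @return An object of class `field_state`.
#' @export
field_state <- function(u, v, t = 0) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  structure(list(u = u, v = v, t = t), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("Field state at t = %g: %d x %d, u in [%.4g, %.4g]\n",
              x$t, nrow(x$u), ncol(x$u), min(x$u), max(x$u)))
  invisible(x)
}

#' Advance a field state
#'
#' Low-level stepper: applies `nsteps` ADI + Heun steps under the given
#' forcing.  Each step is an implicit-x/explicit-y diffusion half-step, a
#' full-step Heun reaction update (forcing evaluated at the step start for
#' the predictor and at the step end for the corrector), then an
#' implicit-y/explicit-x half-step, with the leading axis alternating between
#' steps.  The inhibitor diffuses with coefficient `sigma * c` and its
#' reaction term carries `sigma`.
#'
#' @param state A [field_state()].
#' @param config A [simulation_config()] (supplies params, `dx`, `dt`).
#' @param forcing An [le_forcing()]; defaults to unforced.
#' @param nsteps Number of `dt` steps.
#' @param t_local Stage-local time of the first step (enters the forcing
#'   phase); defaults to `state$t`.
#' @param kinetics Set `FALSE` to run pure diffusion (used by the scheme's
#'   verification tests).
#' @param parity Axis-alternation parity of the first step (0 = x first).
#' @return The advanced `field_state` (time incremented by `nsteps * dt`).
#' @export
pde_step <- function(state, config, forcing = le_forcing(0), nsteps = 1,
                     t_local = NULL, kinetics = TRUE, parity = 0) {
  stopifnot(inherits(state, "field_state"),
            inherits(config, "simulation_config"),
            inherits(forcing, "le_forcing"))
  if (is.null(t_local)) t_local <- state$t
  p <- config$params
  res <- cpp_run_stage(state$u, state$v, p$a, p$b, p$sigma, p$c,
                       forcing$A, forcing$T, config$dx, config$dt,
                       as.integer(nsteps), t_local, 0L, kinetics,
                       as.integer(parity))
  field_state(res$u, res$v, t = state$t + nsteps * config$dt)
}

# run one stage, collecting coarse snapshots plus a dense tail used for
# classification; returns updated state, snapshots, and parity
run_stage_internal <- function(state, stage, config, parity, t_offset) {
  p <- config$params
  f <- stage$forcing
  nsteps <- max(1L, round(stage$duration / config$dt))
  # dense tail: last max(10, 2T) time units sampled so that the window spans
  # at least one forcing period with >= 16 frames
  tail_time <- min(stage$duration, max(10, 2 * f$T))
  tail_stride <- max(1L, round(tail_time / 20 / config$dt))
  tail_steps <- min(nsteps, round(tail_time / config$dt))
  main_steps <- nsteps - tail_steps
  coarse_stride <- max(1L, round(config$snapshot_interval / config$dt))

  snaps <- list()
  if (main_steps > 0L) {
    r1 <- cpp_run_stage(state$u, state$v, p$a, p$b, p$sigma, p$c,
                        f$A, f$T, config$dx, config$dt,
                        as.integer(main_steps), 0, as.integer(coarse_stride),
                        TRUE, as.integer(parity))
    parity <- r1$parity
    snaps <- c(snaps, mapply(function(u, v, t)
      field_state(u, v, t = t_offset + t),
      r1$snap_u, r1$snap_v, r1$snap_t, SIMPLIFY = FALSE))
    state <- field_state(r1$u, r1$v, t = t_offset + r1$t_end)
  }
  r2 <- cpp_run_stage(state$u, state$v, p$a, p$b, p$sigma, p$c,
                      f$A, f$T, config$dx, config$dt,
                      as.integer(tail_steps), main_steps * config$dt,
                      as.integer(tail_stride), TRUE, as.integer(parity))
  tail_snaps <- mapply(function(u, v, t)
    field_state(u, v, t = t_offset + t),
    r2$snap_u, r2$snap_v, r2$snap_t, SIMPLIFY = FALSE)
  state <- field_state(r2$u, r2$v, t = t_offset + nsteps * config$dt)
  list(state = state, parity = r2$parity,
       snapshots = c(snaps, tail_snaps), tail_snapshots = tail_snaps)
}

#' Run a staged forcing protocol
#'
#' Integrates the configured stages in order with a continuous field state
#' across stage boundaries; the forcing phase restarts at zero at each stage
#' onset.  Snapshots are collected at `snapshot_interval`, densified over the
#' final stretch of each stage, and each stage's closing window is classified
#' with [classify_pattern()].
#'
#' @param config A [simulation_config()].
#' @param init Optional initial [field_state()] (e.g. a settled pattern for
#'   bistability protocols); defaults to [initialize_fields()].
#' @return An object of class `protocol_result`: list with `stages` (per
#'   stage: the stage, its `pattern_report`, and the classification
#'   snapshots), `snapshots` (all frames, absolute time), `final` state and
#'   the `config`.
#' @examples
#' \donttest{
#' cfg <- fast_config(a = 25, stages = list(protocol_stage(150)), seed = 1)
#' res <- run_protocol(cfg)
#' res$stages[[1]]$report
#' }
#' @export
run_protocol <- function(config, init = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  state <- if (is.null(init)) initialize_fields(config) else init
  parity <- 0L
  t_offset <- state$t
  stage_out <- list()
  all_snaps <- list()
  for (s in seq_along(config$stages)) {
    stage <- config$stages[[s]]
    run <- run_stage_internal(state, stage, config, parity, t_offset)
    state <- run$state
    parity <- run$parity
    t_offset <- state$t
    report <- classify_pattern(run$tail_snapshots, config$dx)
    stage_out[[s]] <- list(stage = stage, report = report,
                           snapshots = run$tail_snapshots)
    all_snaps <- c(all_snaps, run$snapshots)
  }
  structure(list(stages = stage_out, snapshots = all_snaps, final = state,
                 config = config),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Protocol run: %d stage(s), final t = %g\n",
              length(x$stages), x$final$t))
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cat(sprintf("  stage %d (A = %g, T = %g, duration %g): %s (k = %.3g)\n",
                i, st$stage$forcing$A, st$stage$forcing$T,
                st$stage$duration, st$report$label, st$report$dominant_k))
  }
  invisible(x)
}
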