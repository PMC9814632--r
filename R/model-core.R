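#' Dimensionless Lengyel-Epstein model parameters
#'
#' Container for the kinetic and diffusion parameters of the nondimensional
#' Lengyel-Epstein activator-inhibitor model of the CIMA reaction.  `a` and `b`
#' are the dimensionless feed parameters (activator supply and inhibitor
#' production), `sigma = 1 + K` is the rescaling induced by the reversible
#' triiodide-starch complexation (slows the activator), and `c = D_Y / D_X` is
#' the inhibitor-to-activator diffusivity ratio.
#'
#' @param a Feed parameter of the activator supply; positive.
#' @param b Feed parameter of the inhibitor production; positive.
#' @param sigma Rescaling parameter, `>= 1`.
#' @param c Diffusivity ratio `D_Y / D_X`, positive.
#' @return An object of class `le_params`.
#' @examples
#' p <- le_params(a = 22)
#' steady_state(p)
#' @export
le_params <- function(a, b = 1.9, sigma = 8, c = 1.5) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (a <= 0) stop("'a' must be > 0")
  if (b <= 0) stop("'b' must be > 0")
  if (sigma < 1) stop("'sigma' must be >= 1")
  if (c <= 0) stop("'c' must be > 0")
  structure(list(a = a, b = b, sigma = sigma, c = c), class = "le_params")
}

#' @export
print.le_params <- function(x, ...) {
  cat(sprintf("Lengyel-Epstein parameters: a = %g, b = %g, sigma = %g, c = %g\n",
              x$a, x$b, x$sigma, x$c))
  invisible(x)
}

#' Sinusoidal forcing of the feed parameter
#'
#' Amplitude `A` and period `T` of the sinusoidal modulation applied to the
#' feed parameter `a`; `A = 0` recovers the unforced (autonomous) model.
#'
#' @param A Forcing amplitude, in the units of `a`; nonnegative.
#' @param T Forcing period in dimensionless time; positive.
#' @return An object of class `le_forcing`.
#' @export
le_forcing <- function(A = 0, T = 1) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(T), length(T) == 1L, is.finite(T))
  if (A < 0) stop("'A' must be >= 0")
  if (T <= 0) stop("'T' must be > 0")
  structure(list(A = A, T = T), class = "le_forcing")
}

#' @export
print.le_forcing <- function(x, ...) {
  cat(sprintf("Feed forcing: A = %g, T = %g\n", x$A, x$T))
  invisible(x)
}

#' Effective feed value under forcing
#'
#' Evaluates `a + A * sin(2 * pi * t / T)`, the instantaneous feed parameter of
#' the forced model.  Vectorized over `t`.
#'
#' @param params An [le_params] object.
#' @param forcing An [le_forcing] object.
#' @param t Time(s), dimensionless.
#' @return Numeric vector of effective feed values.
#' @export
forcing_value <- function(params, forcing, t) {
  stopifnot(inherits(params, "le_params"), inherits(forcing, "le_forcing"))
  if (!all(is.finite(t))) stop("'t' must be finite")
  params$a + forcing$A * sin(2 * pi * t / forcing$T)
}

#' Reaction terms of the forced model
#'
#' Space-free kinetics of the forced Lengyel-Epstein model:
#' `du/dt = a + A sin(2 pi t / T) - u - 4 u v / (1 + u^2)` and
#' `dv/dt = sigma * b * (u - u v / (1 + u^2))`.
#' Negative states are evaluated as written; positivity monitoring is the
#' caller's (solver's) responsibility.
#'
#' @param u,v Activator (iodide) and inhibitor (chlorite) concentrations,
#'   dimensionless.  Vectorized.
#' @param params An [le_params] object.
#' @param forcing An [le_forcing] object; defaults to no forcing.
#' @param t Time at which the forcing is evaluated.
#' @return List with components `du` and `dv`.
#' @export
reaction_terms <- function(u, v, params, forcing = le_forcing(0), t = 0) {
  stopifnot(inherits(params, "le_params"), inherits(forcing, "le_forcing"))
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("state must be finite")
  w <- u * v / (1 + u^2)
  f <- forcing_value(params, forcing, t)
  list(du = f - u - 4 * w,
       dv = params$sigma * params$b * (u - w))
}

#' Homogeneous steady state of the unforced model
#'
#' Returns the uniform fixed point `u* = a/5`, `v* = 1 + a^2/25` at which the
#' unforced reaction terms vanish identically.
#'
#' @param params An [le_params] object.
#' @return Named numeric vector `c(u, v)`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "le_params"))
  c(u = params$a / 5, v = 1 + params$a^2 / 25)
}

#' Jacobian of the reaction terms
#'
#' Partial derivatives of the space-free kinetics with respect to `(u, v)`,
#' evaluated at a state point.  The forcing enters the kinetics additively and
#' therefore does not appear in the Jacobian.
#'
#' @param u,v State point (scalars).
#' @param params An [le_params] object.
#' @return A 2 x 2 numeric matrix.
#' @export
le_jacobian <- function(u, v, params) {
  stopifnot(inherits(params, "le_params"),
            length(u) == 1L, length(v) == 1L,
            is.finite(u), is.finite(v))
  s <- 1 + u^2
  j11 <- -1 + 4 * v * (u^2 - 1) / s^2
  j12 <- -4 * u / s
  j21 <- params$sigma * params$b * (1 + v * (u^2 - 1) / s^2)
  j22 <- -params$sigma * params$b * u / s
  matrix(c(j11, j21, j12, j22), nrow = 2L, ncol = 2L)
}
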