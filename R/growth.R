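#' Gompertz growth parameters
#'
#' The Gompertz model used here is parametrized by the tumor doubling
#' time rather than an abstract rate:
#' `dT/dt = a T ln(theta_g / T)` with
#' `a = (1/tau_g) ln( ln(theta_g/T0) / ln(theta_g/(2 T0)) )`,
#' which enforces `T(tau_g) = 2 T0` exactly.
#'
#' @param tau_g Doubling time in days (> 0).
#' @param theta_g Plateau volume in mm^3 (fixed, never estimated).
#' @param T0 Initial volume in mm^3; must satisfy `0 < T0 < theta_g/2`
#'   so the rate coefficient is finite and positive.
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(tau_g, theta_g = 1e6, T0) {
  stopifnot(tau_g > 0, theta_g > 0, T0 > 0)
  if (T0 >= theta_g / 2) {
    stop("T0 must be below theta_g/2 for the doubling-time parametrization")
  }
  structure(list(tau_g = tau_g, theta_g = theta_g, T0 = T0),
            class = "gompertz_params")
}

#' Exponential growth parameters
#'
#' Comparison model `T(t) = T0 * 2^(t/tau_g)`, appropriate while tumors
#' are far from the plateau.
#' @param tau_g Doubling time in days.
#' @param T0 Initial volume in mm^3.
#' @export
exponential_params <- function(tau_g, T0) {
  stopifnot(tau_g > 0, T0 > 0)
  structure(list(tau_g = tau_g, T0 = T0), class = "exponential_params")
}

#' Gompertz rate coefficient from the doubling time
#'
#' @param params A [gompertz_params()] object.
#' @return The per-day rate coefficient
#'   `a = ln( ln(theta_g/T0) / ln(theta_g/(2 T0)) ) / tau_g` (> 0).
#' @export
gompertz_rate <- function(params) {
  with(params, log(log(theta_g / T0) / log(theta_g / (2 * T0))) / tau_g)
}

#' Closed-form untreated Gompertz trajectory
#'
#' `T(t) = theta_g * (T0/theta_g)^(exp(-a t))`, the exact solution of
#' the untreated model; strictly increasing from `T0` to the plateau.
#'
#' @param params A [gompertz_params()] object.
#' @param t Times in days (>= 0; vectorized).
#' @return Volumes in mm^3.
#' @examples
#' p <- gompertz_params(tau_g = 10, T0 = 5)
#' gompertz_closed_form(p, c(0, 10))  # 5, 10: doubles at t = tau_g
#' @export
gompertz_closed_form <- function(params, t) {
  stopifnot(all(t >= 0))
  a <- gompertz_rate(params)
  with(params, theta_g * (T0 / theta_g)^exp(-a * t))
}

#' Numerically integrated untreated Gompertz trajectory
#'
#' Adaptive integration of the growth ODE; serves as a cross-check of
#' [gompertz_closed_form()], which is the production path.
#'
#' @param params A [gompertz_params()] object.
#' @param times Strictly increasing grid starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return Volumes in mm^3 at `times`.
#' @export
gompertz_ode <- function(params, times, rtol = 1e-8, atol = 1e-8) {
  stopifnot(times[1L] == 0, all(diff(times) > 0) || length(times) == 1L)
  if (length(times) == 1L) return(params$T0)
  a <- gompertz_rate(params)
  deriv <- function(t, state, parms) {
    list(a * state[1L] * log(params$theta_g / state[1L]))
  }
  sol <- deSolve::ode(y = c(T = params$T0), times = times, func = deriv,
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) stop("Gompertz ODE integration failed")
  unname(sol[, "T"])
}

#' Exponential trajectory
#'
#' @param params An [exponential_params()] object.
#' @param t Times in days (>= 0; vectorized).
#' @return `T0 * 2^(t/tau_g)`.
#' @export
exponential_model <- function(params, t) {
  stopifnot(all(t >= 0))
  with(params, T0 * 2^(t / tau_g))
}
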