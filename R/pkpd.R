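#' Two-compartment pharmacokinetic constants
#'
#' Linear two-compartment model for 5-fluorouracil: plasma
#' concentration `C1` and tumor-site concentration `C2` (both ng/ml)
#' with first-order transfer (`k12`, `k21`), elimination from plasma
#' (`k10`) and distribution volumes `V1`, `V2` (ml). Defaults are
#' literature values for 5-FU. Elimination is fast (`k10` = 151.2/day,
#' a ~10-minute plasma half-life) while the tumor compartment drains at
#' the slow eigenvalue (about 2.2/day), so weekly boluses do not
#' accumulate.
#'
#' @param k10,k12,k21 Rate constants in 1/day.
#' @param V1,V2 Distribution volumes in ml.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(k10 = 151.2, k12 = 5.62, k21 = 2.31,
                      V1 = 0.71e3, V2 = 0.1e3) {
  stopifnot(k10 > 0, k12 > 0, k21 > 0, V1 > 0, V2 > 0)
  structure(list(k10 = k10, k12 = k12, k21 = k21, V1 = V1, V2 = V2),
            class = "pk_params")
}

#' Pharmacodynamic parameters
#'
#' Threshold log-kill model: the cell-loss rate is
#' `L = k_eff * (C2 - c2_thr) * T` when `C2 >= c2_thr` and 0 below the
#' threshold (Heaviside gate).
#'
#' @param k_eff Drug kill rate in ml/(day*ng), >= 0.
#' @param c2_thr Therapeutic threshold in ng/ml, >= 0.
#' @export
pd_params <- function(k_eff, c2_thr = 0) {
  stopifnot(k_eff >= 0, c2_thr >= 0)
  structure(list(k_eff = k_eff, c2_thr = c2_thr), class = "pd_params")
}

#' System eigenvalues of the two-compartment model
#'
#' Roots of `lambda^2 + (k10+k12+k21) lambda + k10 k21 = 0`; both are
#' real and negative for positive rate constants (the discriminant
#' equals `(k10+k12-k21)^2 + 4 k12 k21 > 0`).
#'
#' @param pk A [pk_params()] object.
#' @return `c(slow, fast)` eigenvalues in 1/day (slow > fast).
#' @export
pk_eigenvalues <- function(pk) {
  s <- pk$k10 + pk$k12 + pk$k21
  disc <- s^2 - 4 * pk$k10 * pk$k21
  sq <- sqrt(disc)
  c(slow = (-s + sq) / 2, fast = (-s - sq) / 2)
}

#' Concentrations after a single bolus dose
#'
#' An intraperitoneal bolus is modelled as an impulse that raises the
#' plasma concentration by `dose_ng / V1` at the dose time; the tumor
#' compartment then fills and drains biexponentially:
#' `C2(t) = dose k12 / (V2 (l1-l2)) * (exp(l1 t) - exp(l2 t))`.
#'
#' @param pk A [pk_params()] object.
#' @param dose_ng Absolute dose in ng (> 0).
#' @param t Times since the dose in days (>= 0; vectorized).
#' @return A list with numeric vectors `c1` and `c2` (ng/ml).
#' @export
pk_single_dose <- function(pk, dose_ng, t) {
  stopifnot(dose_ng > 0, all(t >= 0))
  ev <- pk_eigenvalues(pk)
  l1 <- ev[["slow"]]; l2 <- ev[["fast"]]
  e1 <- exp(l1 * t); e2 <- exp(l2 * t)
  c1 <- dose_ng / (pk$V1 * (l1 - l2)) * ((l1 + pk$k21) * e1 - (l2 + pk$k21) * e2)
  c2 <- dose_ng * pk$k12 / (pk$V2 * (l1 - l2)) * (e1 - e2)
  list(c1 = pmax(c1, 0), c2 = pmax(c2, 0))
}

# vectorized superposition of single-dose solutions; zero before each dose
pk_conc_at <- function(pk, dose_days, dose_ng, t) {
  c1 <- numeric(length(t)); c2 <- numeric(length(t))
  for (i in seq_along(dose_days)) {
    u <- t - dose_days[i]
    on <- u >= 0
    if (!any(on)) next
    sol <- pk_single_dose(pk, dose_ng[i], u[on])
    c1[on] <- c1[on] + sol$c1
    c2[on] <- c2[on] + sol$c2
  }
  list(c1 = c1, c2 = c2)
}

#' Concentration profile under a dosing schedule
#'
#' Superposes single-dose solutions (the PK system is linear) on a time
#' grid. The returned profile also carries the schedule and constants so
#' downstream code can evaluate concentrations analytically at arbitrary
#' times.
#'
#' @param pk A [pk_params()] object.
#' @param dose_days Sorted dose times in days.
#' @param dose_ng Absolute doses in ng (recycled to the schedule length).
#' @param times Evaluation grid (days); must start at or before no dose.
#' @return An object of class `concentration_profile` with fields
#'   `times`, `c1`, `c2`, `dose_days`, `dose_ng`, `pk`.
#' @export
pk_schedule <- function(pk, dose_days, dose_ng, times) {
  stopifnot(length(dose_days) >= 1L, all(diff(dose_days) > 0),
            all(dose_ng > 0))
  dose_ng <- rep_len(dose_ng, length(dose_days))
  if (min(dose_days) < min(times)) {
    stop("dose precedes the start of the evaluation grid")
  }
  conc <- pk_conc_at(pk, dose_days, dose_ng, times)
  structure(list(times = as.numeric(times), c1 = conc$c1, c2 = conc$c2,
                 dose_days = as.numeric(dose_days),
                 dose_ng = as.numeric(dose_ng), pk = pk),
            class = "concentration_profile")
}

#' Exact per-dose areas under the concentration curves
#'
#' Closed-form infinite-horizon integrals of the single-dose solution:
#' `AUC1 = dose / (k10 V1)` and `AUC2 = (k12 V1)/(k21 V2) * AUC1`.
#'
#' @param pk A [pk_params()] object.
#' @param dose_ng Dose in ng.
#' @return List with `auc1` and `auc2` (ng*day/ml).
#' @export
pk_auc <- function(pk, dose_ng) {
  auc1 <- dose_ng / (pk$k10 * pk$V1)
  list(auc1 = auc1, auc2 = (pk$k12 * pk$V1) / (pk$k21 * pk$V2) * auc1)
}

#' Threshold kill term
#'
#' Cell-loss rate of the pharmacodynamic model:
#' 0 when `C2 < c2_thr`, otherwise `k_eff * (C2 - c2_thr) * T`. The
#' loss is continuous at the threshold (the gate opens on a zero
#' driving term).
#'
#' @param T_vol Tumor volume in mm^3 (> 0; vectorized).
#' @param c2 Tumor-site concentration in ng/ml.
#' @param pd A [pd_params()] object.
#' @return Loss rate in mm^3/day.
#' @export
kill_rate <- function(T_vol, c2, pd) {
  stopifnot(all(T_vol > 0))
  pd$k_eff * pmax(c2 - pd$c2_thr, 0) * T_vol
}

# exp-convolution kernel (e^{l u} - e^{-a u})/(l + a), with the
# confluent limit u e^{l u} when l + a ~ 0
conv_kernel <- function(l, a, u) {
  d <- l + a
  if (abs(d) < 1e-10 * max(abs(l), abs(a), 1)) {
    u * exp(l * u)
  } else {
    (exp(l * u) - exp(-a * u)) / d
  }
}

# Exact kill integral K(t) = int_0^t e^{-a(t-s)} C2(s) ds for an
# impulse-train schedule (threshold 0): per-dose biexponential
# convolution in closed form.
kill_integral_analytic <- function(a, profile, t) {
  ev <- pk_eigenvalues(profile$pk)
  l1 <- ev[["slow"]]; l2 <- ev[["fast"]]
  K <- numeric(length(t))
  for (i in seq_along(profile$dose_days)) {
    u <- t - profile$dose_days[i]
    on <- u > 0
    if (!any(on)) next
    A <- profile$dose_ng[i] * profile$pk$k12 / (profile$pk$V2 * (l1 - l2))
    K[on] <- K[on] + A * (conv_kernel(l1, a, u[on]) - conv_kernel(l2, a, u[on]))
  }
  K
}

# Numeric kill integral for c2_thr > 0: recursive exponentially
# weighted trapezoid of f(s) = max(C2(s) - thr, 0) on a grid refined
# after each dose (C2 equilibrates on the 1/(k10+k12+k21) time scale).
kill_integral_numeric <- function(a, profile, c2_thr, t) {
  t_end <- max(t)
  grid <- seq(0, t_end, by = 0.01)
  for (td in profile$dose_days) {
    fine <- seq(td, min(td + 0.5, t_end), by = 2e-4)
    grid <- c(grid, fine)
  }
  grid <- sort(unique(c(grid, t)))
  f <- pmax(pk_conc_at(profile$pk, profile$dose_days, profile$dose_ng,
                       grid)$c2 - c2_thr, 0)
  K <- numeric(length(grid))
  for (i in seq_len(length(grid) - 1L)) {
    dt <- grid[i + 1L] - grid[i]
    w <- exp(-a * dt)
    K[i + 1L] <- K[i] * w + dt / 2 * (f[i + 1L] + f[i] * w)
  }
  K[match(t, grid)]
}

#' Simulate a treated tumor trajectory
#'
#' Couples the Gompertz growth model to the threshold kill term driven
#' by the tumor-site concentration. Because the model is linear in
#' `ln T`, the solution has the closed form
#' `ln T(t) = ln theta_g + (ln T0 - ln theta_g) e^{-a t} - k_eff K(t)`
#' with `K(t) = int_0^t e^{-a(t-s)} (C2(s) - c2_thr)_+ ds`. With a zero
#' threshold `K` is evaluated exactly (biexponential convolution); with
#' a positive threshold it is computed by exponentially weighted
#' quadrature on a dose-refined grid. `method = "ode"` instead
#' integrates the volume ODE directly with an adaptive solver and is
#' retained as an independent cross-check.
#'
#' @param g A [gompertz_params()] object (clock zero = first
#'   observation of the series).
#' @param pd A [pd_params()] object.
#' @param profile A [pk_schedule()] concentration profile whose dose
#'   schedule is on the same clock.
#' @param times Output times in days (>= 0).
#' @param method `"analytic"` (default) or `"ode"`.
#' @param rtol,atol Solver tolerances for `method = "ode"`.
#' @return Volumes in mm^3 at `times`. With `k_eff = 0`, or a threshold
#'   above the peak concentration, this equals the untreated closed
#'   form; for `k_eff > 0` the treated trajectory is dominated by the
#'   untreated one at all times.
#' @export
simulate_treated <- function(g, pd, profile, times,
                             method = c("analytic", "ode"),
                             rtol = 1e-10, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(all(times >= 0))
  a <- gompertz_rate(g)
  if (method == "analytic") {
    K <- if (pd$c2_thr == 0) {
      kill_integral_analytic(a, profile, times)
    } else {
      kill_integral_numeric(a, profile, pd$c2_thr, times)
    }
    u <- log(g$theta_g) + (log(g$T0) - log(g$theta_g)) * exp(-a * times) -
      pd$k_eff * K
    return(exp(u))
  }
  # direct ODE on ln T; output grid refined after each dose so the
  # solver resolves the fast concentration transient
  o <- order(times)
  t_end <- max(times)
  grid <- sort(unique(c(times, seq(0, t_end, by = 0.05),
                        unlist(lapply(profile$dose_days, function(td) {
                          seq(td, min(td + 0.5, t_end), by = 1e-3)
                        })))))
  grid <- grid[grid >= 0]
  deriv <- function(t, state, parms) {
    c2 <- pk_conc_at(profile$pk, profile$dose_days, profile$dose_ng, t)$c2
    list(a * (log(g$theta_g) - state[1L]) -
           pd$k_eff * max(c2 - pd$c2_thr, 0))
  }
  sol <- deSolve::lsoda(y = c(u = log(g$T0)), times = grid, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) stop("treated-tumor ODE integration failed")
  exp(sol[match(times, grid), "u"])
}
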