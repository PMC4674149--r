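#' Normalized mean squared error
#'
#' `NMSE = 100 * sum((y - yhat)^2) / sum(y^2)`, in percent. Values near
#' 0 indicate a good fit; the measure is invariant to joint rescaling
#' of both vectors, so it does not depend on measurement units.
#'
#' @param observed,predicted Equal-length numeric vectors of volumes.
#' @return NMSE in percent.
#' @examples
#' nmse(c(1, 2), c(2, 1))  # 40
#' @export
nmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1L)
  denom <- sum(observed^2)
  if (denom == 0) stop("NMSE undefined: observed values are all zero")
  100 * sum((observed - predicted)^2) / denom
}

fit_result <- function(estimate, nmse_percent, n_obs, converged, at_bound,
                       residuals, status = "ok") {
  structure(
    list(estimate = estimate, nmse_percent = nmse_percent, n_obs = n_obs,
         converged = converged, at_bound = at_bound, residuals = residuals,
         status = status),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("fit_result: ", x$status, " (n_obs = ", x$n_obs, ")\n", sep = "")
    return(invisible(x))
  }
  est <- paste(sprintf("%s = %.6g", names(x$estimate), x$estimate),
               collapse = ", ")
  cat(sprintf("fit_result: %s | NMSE %.2f%% | n = %d%s%s\n", est,
              x$nmse_percent, x$n_obs,
              if (x$converged) "" else " | NOT CONVERGED",
              if (x$at_bound) " | at bound" else ""))
  invisible(x)
}

excluded_result <- function(n_obs, why) {
  fit_result(estimate = NA_real_, nmse_percent = NA_real_, n_obs = n_obs,
             converged = FALSE, at_bound = FALSE, residuals = NULL,
             status = why)
}

#' Is a fit an exclusion?
#' @param fit A `fit_result`.
#' @return `TRUE` when the tumor was excluded (insufficient data).
#' @export
is_excluded <- function(fit) {
  inherits(fit, "fit_result") && fit$status != "ok"
}

# bounded 1-D Levenberg-Marquardt with multistart; residual_fn(par)
# returns the residual vector. Starts are log-spaced in [lo', hi] with
# lo' floored away from zero so log spacing is defined.
multistart_lm <- function(residual_fn, bounds, n_starts) {
  lo <- bounds[1L]; hi <- bounds[2L]
  lo_pos <- if (lo > 0) lo else hi * 1e-8
  starts <- exp(seq(log(lo_pos), log(hi), length.out = n_starts))
  if (lo == 0) starts <- c(0, starts[-1L])
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lo, upper = hi, fn = residual_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssq <- sum(fit$fvec^2)
    if (is.null(best) || ssq < best$ssq) {
      best <- list(par = fit$par, ssq = ssq, info = fit$info)
    }
  }
  if (is.null(best)) stop("all multistart fits failed")
  # no-worsening guarantee against the raw starts themselves
  for (s in starts) {
    ssq_s <- sum(residual_fn(s)^2)
    if (ssq_s < best$ssq) best <- list(par = s, ssq = ssq_s, info = 0L)
  }
  best
}

used_pretreatment <- function(series) {
  if (is.null(series$treatment_start_day)) {
    seq_along(series$days)
  } else {
    which(series$days < series$treatment_start_day)
  }
}

#' Estimate the tumor doubling time
#'
#' Nonlinear least squares on raw volumes against the untreated
#' Gompertz closed form, with `T0` fixed to the first used volume and
#' `theta_g` taken from the configuration. For treated series only
#' observations strictly before `treatment_start_day` are used. Series
#' with fewer than `cfg$fit$min_obs` usable points are excluded (status
#' `"excluded: insufficient observations"`), mirroring the study's
#' exclusion of tumors with insufficient pre-treatment data.
#'
#' @param series A [tumor_series()].
#' @param cfg A [study_config()].
#' @return A `fit_result` with `estimate["tau_g"]` (days), the NMSE of
#'   the fitted curve against the used observations, convergence and
#'   bound flags, and raw residuals.
#' @export
fit_tau_g <- function(series, cfg = study_config()) {
  idx <- used_pretreatment(series)
  if (length(idx) < cfg$fit$min_obs) {
    return(excluded_result(length(idx), "excluded: insufficient observations"))
  }
  days <- series$days[idx] - series$days[idx][1L]
  vols <- series$volumes[idx]
  T0 <- vols[1L]
  bounds <- cfg$fit$tau_bounds
  resid_fn <- function(tau) {
    p <- gompertz_params(tau_g = tau, theta_g = cfg$theta_g, T0 = T0)
    vols - gompertz_closed_form(p, days)
  }
  best <- multistart_lm(resid_fn, bounds, cfg$fit$multistarts)
  pred <- vols - resid_fn(best$par)
  tol <- 1e-6 * diff(bounds)
  fit_result(
    estimate = c(tau_g = best$par), nmse_percent = nmse(vols, pred),
    n_obs = length(idx), converged = best$info %in% 0:3,
    at_bound = best$par <= bounds[1L] + tol || best$par >= bounds[2L] - tol,
    residuals = vols - pred
  )
}

#' Estimate the doubling time with the exponential model
#'
#' As [fit_tau_g()] but against `T(t) = T0 * 2^(t/tau_g)`. On data
#' generated by a Gompertz process the two estimates agree at early
#' times and diverge as the tumor feels the plateau.
#'
#' @inheritParams fit_tau_g
#' @return A `fit_result` with `estimate["tau_g"]`.
#' @export
fit_exponential <- function(series, cfg = study_config()) {
  idx <- used_pretreatment(series)
  if (length(idx) < cfg$fit$min_obs) {
    return(excluded_result(length(idx), "excluded: insufficient observations"))
  }
  days <- series$days[idx] - series$days[idx][1L]
  vols <- series$volumes[idx]
  T0 <- vols[1L]
  bounds <- cfg$fit$tau_bounds
  resid_fn <- function(tau) {
    vols - exponential_model(exponential_params(tau_g = tau, T0 = T0), days)
  }
  best <- multistart_lm(resid_fn, bounds, cfg$fit$multistarts)
  pred <- vols - resid_fn(best$par)
  tol <- 1e-6 * diff(bounds)
  fit_result(
    estimate = c(tau_g = best$par), nmse_percent = nmse(vols, pred),
    n_obs = length(idx), converged = best$info %in% 0:3,
    at_bound = best$par <= bounds[1L] + tol || best$par >= bounds[2L] - tol,
    residuals = vols - pred
  )
}

#' Estimate the drug kill rate
#'
#' With the doubling time fixed from the pre-treatment fit, estimates
#' `k_eff >= 0` by least squares of the treated simulator against the
#' post-onset observations (days at or after the first dose). The
#' treated trajectory is simulated from the start of the series with
#' `T0` fixed to the first volume. Because the log-space solution is
#' linear in `k_eff`, the kill integral is precomputed once and each
#' objective evaluation is closed-form. Estimates pinned at a bound
#' (in particular at zero for non-responding tumors) set `at_bound`.
#'
#' @param series A [tumor_series()] with `treatment_start_day` set.
#' @param tau_g Fixed doubling time in days (from [fit_tau_g()]).
#' @param dose_days,dose_ng Dosing schedule on the series clock
#'   (absolute doses in ng, e.g. from [resolve_dose_ng()]).
#' @param cfg A [study_config()].
#' @return A `fit_result` with `estimate["k_eff"]` (ml/(day*ng)) and
#'   the NMSE over the post-onset observations.
#' @export
fit_keff <- function(series, tau_g, dose_days, dose_ng,
                     cfg = study_config()) {
  if (is.null(series$treatment_start_day)) {
    stop("fit_keff requires a treated series (treatment_start_day set)")
  }
  post <- which(series$days >= series$treatment_start_day)
  if (length(post) == 0L) stop("no post-treatment observations")
  g <- gompertz_params(tau_g = tau_g, theta_g = cfg$theta_g,
                       T0 = series$volumes[1L])
  a <- gompertz_rate(g)
  profile <- pk_schedule(cfg$pk, dose_days, dose_ng,
                         times = range(c(0, series$days)))
  t_obs <- series$days[post]
  vols <- series$volumes[post]
  K <- if (cfg$c2_thr == 0) {
    kill_integral_analytic(a, profile, t_obs)
  } else {
    kill_integral_numeric(a, profile, cfg$c2_thr, t_obs)
  }
  base_log <- log(g$theta_g) + (log(g$T0) - log(g$theta_g)) * exp(-a * t_obs)
  bounds <- cfg$fit$keff_bounds
  resid_fn <- function(keff) vols - exp(base_log - keff * K)
  best <- multistart_lm(resid_fn, bounds, cfg$fit$multistarts)
  pred <- vols - resid_fn(best$par)
  tol <- 1e-9 * diff(bounds)
  fit_result(
    estimate = c(k_eff = best$par), nmse_percent = nmse(vols, pred),
    n_obs = length(post), converged = best$info %in% 0:3,
    at_bound = best$par <= bounds[1L] + tol || best$par >= bounds[2L] - tol,
    residuals = vols - pred
  )
}
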