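# Shared builders for noiseless synthetic series and dosing schedules.

twice_weekly <- function(n) seq(0, by = 3.5, length.out = n)

make_gompertz_series <- function(tau_g, T0 = 5, n = 12, theta_g = 1e6,
                                 mouse = "M1", tumor = 1L) {
  days <- twice_weekly(n)
  p <- gompertz_params(tau_g = tau_g, theta_g = theta_g, T0 = T0)
  tumor_series(mouse, tumor, days, gompertz_closed_form(p, days))
}

# treated series simulated noiselessly from the coupled model
make_treated_series <- function(tau_g, k_eff, T0 = 5, n_pre = 8, n_post = 10,
                                dose_ng = 1.25e6, c2_thr = 0,
                                theta_g = 1e6, mouse = "M1", tumor = 1L) {
  days <- twice_weekly(n_pre + n_post)
  onset <- days[n_pre + 1L]
  dose_days <- seq(onset, max(days), by = 7)
  g <- gompertz_params(tau_g = tau_g, theta_g = theta_g, T0 = T0)
  profile <- pk_schedule(pk_params(), dose_days, dose_ng, range(days))
  vols <- simulate_treated(g, pd_params(k_eff, c2_thr), profile, days)
  list(series = tumor_series(mouse, tumor, days, vols,
                             treatment_start_day = onset),
       dose_days = dose_days,
       dose_ng = rep(dose_ng, length(dose_days)))
}

# piecewise numeric integration of the two-compartment system with
# impulse doses; independent oracle for the analytic superposition
integrate_pk_numeric <- function(pk, dose_days, dose_ng, times,
                                 rtol = 1e-12, atol = 1e-12) {
  dose_ng <- rep_len(dose_ng, length(dose_days))
  deriv <- function(t, y, p) {
    list(c(pk$k21 * y[2L] * pk$V2 / pk$V1 - (pk$k12 + pk$k10) * y[1L],
           pk$k12 * y[1L] * pk$V1 / pk$V2 - pk$k21 * y[2L]))
  }
  state <- c(0, 0)
  out_c1 <- numeric(length(times)); out_c2 <- numeric(length(times))
  bounds <- c(dose_days, Inf)
  for (k in seq_along(dose_days)) {
    state[1L] <- state[1L] + dose_ng[k] / pk$V1
    seg <- which(times >= bounds[k] & times < bounds[k + 1L])
    t_seg <- sort(unique(c(bounds[k], times[seg],
                           if (is.finite(bounds[k + 1L])) bounds[k + 1L])))
    sol <- deSolve::lsoda(state, t_seg, deriv, NULL, rtol = rtol, atol = atol)
    out_c1[seg] <- sol[match(times[seg], t_seg), 2L]
    out_c2[seg] <- sol[match(times[seg], t_seg), 3L]
    state <- unname(sol[nrow(sol), 2:3])
  }
  list(c1 = out_c1, c2 = out_c2)
}

# measurement-table row block for one tumor from exact diameters
records_from_diameters <- function(mouse, tumor, days, diam, weight = 25) {
  data.frame(mouse_id = mouse, tumor_id = tumor, day = days,
             len1_mm = diam, len2_mm = diam, len3_mm = diam,
             wid1_mm = diam, wid2_mm = diam, wid3_mm = diam,
             weight_g = weight, stringsAsFactors = FALSE)
}
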