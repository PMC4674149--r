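#' Synthetic cohort design
#'
#' Parameters of the synthetic mouse-cohort generator. The defaults
#' emulate the design of the de novo carcinogenesis study: 3 monitored
#' tumors per mouse, twice-weekly triplicate caliper reads, mouse-level
#' doubling times drawn from a fast/slow two-component mixture with
#' additional tumor-level scatter, weekly intraperitoneal boluses at 50
#' or 100 mg/kg starting when the first tumor reaches 3 mm diameter,
#' and sacrifice when any tumor reaches 10 mm.
#'
#' Mixture defaults (fast 10 +/- 2.5 d, slow 28 +/- 6 d, equal weights)
#' bracket the fast/slow group means observed in the untreated cohort;
#' the within-mouse scatter (13 d, rejection-truncated at `tau_floor`)
#' was calibrated by Monte Carlo so that the median between/within
#' mean-square ratio of 8-mouse, 3-tumor cohorts is close to 2.4, the
#' ratio observed in the untreated study arm. The kill rate is coupled
#' to the doubling time as `k_eff = c / tau_g^gamma * exp(N(0, sdlog))`
#' with `gamma = 1` and `c` chosen so the median `k_eff` is about
#' 4e-5 ml/(day*ng), the magnitude of the treated-arm estimates.
#'
#' @param n_untreated Untreated (DMSO) mice.
#' @param n_per_treated_arm Mice in each of the two 5-FU arms.
#' @param tumors_per_mouse Monitored tumors per mouse.
#' @param tau_fast_mean,tau_fast_sd,tau_slow_mean,tau_slow_sd,fast_weight
#'   Two-component mouse-level doubling-time mixture (days).
#' @param within_mouse_sd Tumor-level SD around the mouse doubling time
#'   (days); draws are rejection-truncated at `tau_floor`.
#' @param tau_floor Lower truncation for doubling times (days).
#' @param keff_c,keff_gamma,keff_sdlog Kill-rate law
#'   `k_eff = keff_c / tau_g^keff_gamma * lognormal(sdlog)`.
#' @param read_noise_sdlog Multiplicative lognormal SD of each caliper
#'   read (0.05 = 5% read noise).
#' @param obs_interval Days between observations (3.5 = twice weekly).
#' @param dose_interval Days between doses (weekly).
#' @param arm_doses Named mg/kg dose levels of the treated arms.
#' @param onset_diameter Treatment starts at the first observation where
#'   any tumor diameter reaches this (mm).
#' @param sacrifice_diameter Sacrifice at the first observation where
#'   any tumor diameter reaches this (mm).
#' @param max_days Maximum follow-up (days).
#' @param T0_diameter_range Initial tumor diameters are uniform on this
#'   range (mm); 1-2 mm is the size at which tumors become visible.
#' @param weight_mean,weight_sd Mouse body weight law (g).
#' @param c2_thr Therapeutic threshold used in simulation (ng/ml).
#' @param seed RNG seed for [generate_cohort()].
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_untreated = 8L,
                          n_per_treated_arm = 8L,
                          tumors_per_mouse = 3L,
                          tau_fast_mean = 10, tau_fast_sd = 2.5,
                          tau_slow_mean = 28, tau_slow_sd = 6,
                          fast_weight = 0.5,
                          within_mouse_sd = 13,
                          tau_floor = 1,
                          keff_c = 7.6e-4, keff_gamma = 1,
                          keff_sdlog = 0.5,
                          read_noise_sdlog = 0.05,
                          obs_interval = 3.5,
                          dose_interval = 7,
                          arm_doses = c(`5FU-50` = 50, `5FU-100` = 100),
                          onset_diameter = 3,
                          sacrifice_diameter = 10,
                          max_days = 180,
                          T0_diameter_range = c(1, 2),
                          weight_mean = 25, weight_sd = 2,
                          c2_thr = 0,
                          seed = 1L) {
  stopifnot(n_untreated >= 0L, n_per_treated_arm >= 0L,
            n_untreated + n_per_treated_arm > 0L,
            tumors_per_mouse >= 1L,
            tau_fast_mean > 0, tau_slow_mean > 0,
            tau_fast_sd >= 0, tau_slow_sd >= 0,
            fast_weight >= 0, fast_weight <= 1,
            within_mouse_sd >= 0, tau_floor > 0,
            keff_c >= 0, keff_sdlog >= 0, read_noise_sdlog >= 0,
            obs_interval > 0, dose_interval > 0,
            onset_diameter > 0, sacrifice_diameter > onset_diameter,
            max_days > 0, diff(T0_diameter_range) >= 0,
            T0_diameter_range[1] > 0, weight_mean > 0, weight_sd >= 0,
            c2_thr >= 0)
  structure(as.list(environment()), class = "cohort_design")
}

rtrunc_norm <- function(n, mean, sd, lower, max_try = 1000L) {
  vapply(seq_len(n), function(i) {
    if (sd == 0) {
      if (mean[min(i, length(mean))] <= lower) {
        stop("degenerate truncation: mean at or below the floor with sd = 0")
      }
      return(mean[min(i, length(mean))])
    }
    m <- mean[min(i, length(mean))]
    for (tries in seq_len(max_try)) {
      x <- stats::rnorm(1L, m, sd)
      if (x > lower) return(x)
    }
    stop("truncated draw failed after ", max_try,
         " tries (within-mouse SD too large relative to the mean)")
  }, numeric(1L))
}

#' Draw ground-truth parameters for one mouse
#'
#' Draws the mouse-level doubling time from the fast/slow mixture, adds
#' tumor-level Gaussian scatter (truncated at `tau_floor` by
#' rejection), couples the kill rates to the doubling times through the
#' inverse-power law, and draws a body weight. Uses the current RNG
#' state; [generate_cohort()] seeds it once per cohort.
#'
#' @param design A [cohort_design()].
#' @return A list with `tau_mouse`, vectors `tau_g` and `k_eff` of
#'   length `tumors_per_mouse`, and `weight_g`.
#' @export
sample_mouse_params <- function(design) {
  fast <- stats::runif(1L) < design$fast_weight
  tau_mouse <- if (fast) {
    rtrunc_norm(1L, design$tau_fast_mean, design$tau_fast_sd, design$tau_floor)
  } else {
    rtrunc_norm(1L, design$tau_slow_mean, design$tau_slow_sd, design$tau_floor)
  }
  tau_g <- rtrunc_norm(design$tumors_per_mouse, tau_mouse,
                       design$within_mouse_sd, design$tau_floor)
  k_eff <- design$keff_c / tau_g^design$keff_gamma *
    exp(stats::rnorm(design$tumors_per_mouse, 0, design$keff_sdlog))
  weight_g <- max(stats::rnorm(1L, design$weight_mean, design$weight_sd),
                  design$weight_mean / 2)
  list(tau_mouse = tau_mouse, tau_g = tau_g, k_eff = k_eff,
       weight_g = weight_g)
}

#' Generate a synthetic mouse cohort
#'
#' Forward-simulates every tumor (untreated arm: Gompertz closed form;
#' treated arms: coupled PK/PD from treatment onset), applies the
#' onset and sacrifice rules on the true diameters at observation
#' times, and emits triplicate noisy caliper reads in the measurement
#' schema of [read_measurements()] together with the dose table and the
#' ground-truth parameter table.
#'
#' Identical seeds yield identical cohorts. Tumors are simulated as
#' spheres (length = width = diameter), so the onset/sacrifice
#' thresholds on the geometric-mean diameter reduce to thresholds on
#' the spherical diameter.
#'
#' @param design A [cohort_design()].
#' @return A list with `measurements`, `doses` and `truth` data frames.
#'   `truth` has one row per tumor: `mouse_id, tumor_id, arm,
#'   true_tau_g, true_k_eff, treatment_start_day, last_day`.
#' @export
generate_cohort <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  arms <- c(rep("DMSO", design$n_untreated),
            rep(names(design$arm_doses),
                each = design$n_per_treated_arm))
  meas <- list(); doses <- list(); truth <- list()
  for (m in seq_along(arms)) {
    mouse_id <- sprintf("SM.%02d", m)
    arm <- arms[m]
    sim <- simulate_mouse(design, mouse_id, arm)
    meas[[m]] <- sim$measurements
    doses[[m]] <- sim$doses
    truth[[m]] <- sim$truth
  }
  list(measurements = do.call(rbind, meas),
       doses = do.call(rbind, doses[!vapply(doses, is.null, logical(1L))]),
       truth = do.call(rbind, truth))
}

simulate_mouse <- function(design, mouse_id, arm) {
  pars <- sample_mouse_params(design)
  nt <- design$tumors_per_mouse
  d0 <- stats::runif(nt, design$T0_diameter_range[1L],
                     design$T0_diameter_range[2L])
  T0 <- pi / 6 * d0^3
  grid <- seq(0, design$max_days, by = design$obs_interval)
  gp <- lapply(seq_len(nt), function(j) {
    gompertz_params(tau_g = pars$tau_g[j], theta_g = 1e6, T0 = T0[j])
  })
  untreated <- vapply(gp, gompertz_closed_form, numeric(length(grid)),
                      t = grid)
  treated_arm <- arm != "DMSO"
  onset <- NA_real_
  vols <- untreated
  dose_days <- numeric(0L)
  dose_ng <- numeric(0L)
  if (treated_arm) {
    diam <- sphere_diameter(untreated)
    hit <- which(apply(diam >= design$onset_diameter, 1L, any))
    if (length(hit) > 0L) {
      onset <- grid[hit[1L]]
      dose_days <- seq(onset, design$max_days, by = design$dose_interval)
      dose_ng <- rep(design$arm_doses[[arm]] * pars$weight_g / 1000 * 1e6,
                     length(dose_days))
      profile <- pk_schedule(design_pk(design), dose_days, dose_ng,
                             times = range(grid))
      vols <- vapply(seq_len(nt), function(j) {
        simulate_treated(gp[[j]],
                         pd_params(pars$k_eff[j], design$c2_thr),
                         profile, grid)
      }, numeric(length(grid)))
    }
  }
  # sacrifice at the first observation where any tumor reaches threshold
  diam <- sphere_diameter(vols)
  sac <- which(apply(diam >= design$sacrifice_diameter, 1L, any))
  last_i <- if (length(sac) > 0L) sac[1L] else length(grid)
  keep <- seq_len(last_i)
  last_day <- grid[last_i]
  dose_keep <- dose_days <= last_day
  dose_days <- dose_days[dose_keep]
  dose_ng <- dose_ng[dose_keep]
  if (length(dose_days) == 0L) onset <- NA_real_

  rows <- list()
  for (j in seq_len(nt)) {
    d_true <- sphere_diameter(vols[keep, j])
    nobs <- length(keep)
    len <- matrix(d_true, nobs, 3L) *
      exp(matrix(stats::rnorm(nobs * 3L, 0, design$read_noise_sdlog),
                 nobs, 3L))
    wid <- matrix(d_true, nobs, 3L) *
      exp(matrix(stats::rnorm(nobs * 3L, 0, design$read_noise_sdlog),
                 nobs, 3L))
    rows[[j]] <- data.frame(
      mouse_id = mouse_id, tumor_id = j, day = grid[keep],
      len1_mm = len[, 1L], len2_mm = len[, 2L], len3_mm = len[, 3L],
      wid1_mm = wid[, 1L], wid2_mm = wid[, 2L], wid3_mm = wid[, 3L],
      weight_g = pars$weight_g, stringsAsFactors = FALSE
    )
  }
  dose_df <- if (length(dose_days) > 0L) {
    data.frame(mouse_id = mouse_id, day = dose_days,
               dose_mg_per_kg = design$arm_doses[[arm]],
               stringsAsFactors = FALSE)
  } else NULL
  truth <- data.frame(
    mouse_id = mouse_id, tumor_id = seq_len(nt), arm = arm,
    true_tau_g = pars$tau_g,
    true_k_eff = if (treated_arm) pars$k_eff else NA_real_,
    treatment_start_day = onset, last_day = last_day,
    stringsAsFactors = FALSE
  )
  list(measurements = do.call(rbind, rows), doses = dose_df, truth = truth)
}

design_pk <- function(design) pk_params()

#' Sampling distribution of the cohort rank correlation
#'
#' Generates replicate synthetic cohorts, runs the estimation pipeline
#' on the treated arms of each (doubling time from pre-treatment data,
#' kill rate from post-onset data), and returns the Spearman rank
#' correlation between the per-tumor estimates for each replicate.
#'
#' @param design A [cohort_design()].
#' @param n_reps Number of replicate cohorts (>= 10).
#' @param use_truth Correlate the generative parameters instead of the
#'   fitted ones (faster; isolates the generative coupling from
#'   estimation error).
#' @return Numeric vector of length `n_reps` of Spearman rho values.
#' @export
spearman_structure_check <- function(design, n_reps = 20L,
                                     use_truth = FALSE) {
  stopifnot(n_reps >= 10L)
  vapply(seq_len(n_reps), function(r) {
    d <- design
    d$seed <- design$seed + r
    cohort <- generate_cohort(d)
    if (use_truth) {
      tr <- cohort$truth[!is.na(cohort$truth$true_k_eff), ]
      return(spearman(tr$true_tau_g, tr$true_k_eff)$rho)
    }
    fits <- fit_cohort(cohort$measurements, cohort$doses)
    ok <- !is.na(fits$tau_g) & !is.na(fits$k_eff)
    spearman(fits$tau_g[ok], fits$k_eff[ok])$rho
  }, numeric(1L))
}
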