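test_that("NMSE matches the defining formula and its invariances", {
  expect_equal(nmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nmse(c(1, 2), c(0, 0)), 100)
  expect_equal(nmse(c(1, 2), c(2, 1)), 40)
  expect_error(nmse(c(0, 0), c(1, 1)), "all zero")
  # invariant under joint rescaling (unit independence)
  y <- c(3, 8, 20); yh <- c(2.5, 9, 18)
  expect_equal(nmse(10 * y, 10 * yh), nmse(y, yh))
})

test_that("doubling time is recovered exactly from noise-free series", {
  for (tau in c(5, 10, 30)) {
    fit <- fit_tau_g(make_gompertz_series(tau, T0 = 5, n = 12))
    expect_false(is_excluded(fit))
    expect_equal(unname(fit$estimate["tau_g"]), tau, tolerance = 1e-4)
    expect_lt(fit$nmse_percent, 1e-10)
    expect_true(fit$converged)
    expect_false(fit$at_bound)
  }
})

test_that("series below the minimum observation count are excluded", {
  s2 <- make_gompertz_series(10, n = 2)
  fit <- fit_tau_g(s2)
  expect_true(is_excluded(fit))
  expect_equal(fit$n_obs, 2L)
  expect_true(is.na(fit$estimate))

  # treated series: only strictly pre-treatment points count
  tr <- make_treated_series(10, 5e-5, n_pre = 2, n_post = 8)
  expect_true(is_excluded(fit_tau_g(tr$series)))
  expect_true(is_excluded(fit_exponential(s2)))
})

test_that("pre-treatment fits ignore on-treatment observations", {
  tr <- make_treated_series(12, 3e-3, n_pre = 8, n_post = 10)
  fit <- fit_tau_g(tr$series)
  expect_equal(fit$n_obs, 8L)
  expect_equal(unname(fit$estimate["tau_g"]), 12, tolerance = 1e-6)
})

test_that("kill rate is recovered from noise-free treated series", {
  for (keff in c(5e-5, 1e-3)) {
    tr <- make_treated_series(8, keff)
    fit <- fit_keff(tr$series, tau_g = 8, tr$dose_days, tr$dose_ng)
    expect_equal(unname(fit$estimate["k_eff"]), keff, tolerance = 1e-3)
    expect_false(fit$at_bound)
  }
})

test_that("a null treatment effect pins the kill rate at the lower bound", {
  tr <- make_treated_series(8, 0)
  fit <- fit_keff(tr$series, tau_g = 8, tr$dose_days, tr$dose_ng)
  expect_equal(unname(fit$estimate["k_eff"]), 0)
  expect_true(fit$at_bound)
})

test_that("only the k_eff x dose product is identifiable with a zero threshold", {
  tr1 <- make_treated_series(8, 2e-3, dose_ng = 1.25e6)
  tr2 <- make_treated_series(8, 1e-3, dose_ng = 2.5e6)
  expect_equal(tr1$series$volumes, tr2$series$volumes, tolerance = 1e-12)
})

test_that("exponential fits recover the doubling time and run faster than the data", {
  days <- twice_weekly(10)
  s <- tumor_series("M1", 1L, days,
                    exponential_model(exponential_params(8, 4), days))
  fit <- fit_exponential(s)
  expect_equal(unname(fit$estimate["tau_g"]), 8, tolerance = 1e-4)

  # on Gompertz data reaching a nontrivial fraction of the plateau the
  # exponential estimate is slower (larger tau): late growth decelerates
  g <- gompertz_params(8, 1e3, 5)
  sg <- tumor_series("M1", 1L, days, gompertz_closed_form(g, days))
  fe <- fit_exponential(sg)
  expect_gt(unname(fe$estimate["tau_g"]), 8)
})

test_that("estimates are never worse than any multistart initialization", {
  set.seed(41)
  days <- twice_weekly(10)
  cfg <- study_config()
  for (i in 1:5) {
    vols <- gompertz_closed_form(gompertz_params(runif(1, 4, 40), 1e6, 5),
                                 days) * exp(rnorm(10, 0, 0.1))
    s <- tumor_series("M1", 1L, days, vols)
    fit <- fit_tau_g(s, cfg)
    sse_hat <- sum(fit$residuals^2)
    starts <- exp(seq(log(cfg$fit$tau_bounds[1L]), log(cfg$fit$tau_bounds[2L]),
                      length.out = cfg$fit$multistarts))
    for (tau0 in starts) {
      pred <- gompertz_closed_form(gompertz_params(tau0, 1e6, vols[1L]), days)
      expect_lte(sse_hat, sum((vols - pred)^2) + 1e-9)
    }
  }
})

test_that("doubling-time error shrinks as measurement noise shrinks", {
  set.seed(42)
  days <- twice_weekly(12)
  noise_levels <- c(0.15, 0.05, 0.01)
  err <- vapply(noise_levels, function(sd0) {
    med <- replicate(25, {
      tau <- runif(1, 5, 35)
      vols <- gompertz_closed_form(gompertz_params(tau, 1e6, 5), days) *
        exp(rnorm(12, 0, sd0))
      fit <- fit_tau_g(tumor_series("M1", 1L, days, vols))
      abs(fit$estimate[["tau_g"]] - tau) / tau
    })
    median(med)
  }, numeric(1L))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3L], 0.02)
})
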