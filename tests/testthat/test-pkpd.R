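test_that("eigenvalues solve the characteristic polynomial and set the decay scales", {
  pk <- pk_params()
  ev <- pk_eigenvalues(pk)
  s <- pk$k10 + pk$k12 + pk$k21
  for (l in ev) expect_equal(l^2 + s * l + pk$k10 * pk$k21, 0,
                             tolerance = 1e-9)
  expect_true(all(ev < 0))
  # slow eigenvalue ~ -2.23/day: a week of decay wipes out the dose
  expect_lt(exp(ev[["slow"]] * 7), 1e-6)
})

test_that("single-dose solution honours the impulse convention and the ODE", {
  pk <- pk_params(); D <- 1.25e6
  sol0 <- pk_single_dose(pk, D, 0)
  expect_equal(sol0$c1, D / pk$V1)
  expect_equal(sol0$c2, 0)
  expect_error(pk_single_dose(pk, -1, 0))

  tt <- sort(unique(c(seq(0, 2, by = 1e-3), seq(0, 0.05, length.out = 500))))
  ana <- pk_single_dose(pk, D, tt)
  num <- integrate_pk_numeric(pk, 0, D, tt)
  peak1 <- max(ana$c1); peak2 <- max(ana$c2)
  expect_lt(max(abs(ana$c1 - num$c1)) / peak1, 1e-8)
  expect_lt(max(abs(ana$c2 - num$c2)) / peak2, 1e-8)
  # C2 rises then falls
  i_peak <- which.max(ana$c2)
  expect_gt(i_peak, 1L)
  expect_true(all(diff(ana$c2[1:i_peak]) >= 0))
  expect_true(all(diff(ana$c2[i_peak:length(tt)]) <= 0))
})

test_that("schedules superpose linearly and vanish before the first dose", {
  pk <- pk_params(); D <- 2.5e6
  times <- seq(0, 21, by = 0.01)
  prof1 <- pk_schedule(pk, 7, D, times)
  expect_true(all(prof1$c1[times < 7] == 0))
  single <- pk_single_dose(pk, D, pmax(times - 7, 0))
  on <- times >= 7
  expect_equal(prof1$c2[on], single$c2[on], tolerance = 1e-12)

  prof2 <- pk_schedule(pk, c(7, 14), c(D, D), times)
  prof2x <- pk_schedule(pk, c(7, 14), c(2 * D, 2 * D), times)
  expect_equal(prof2x$c1, 2 * prof2$c1)
  expect_equal(prof2x$c2, 2 * prof2$c2)
  expect_error(pk_schedule(pk, 5, D, seq(6, 10)), "precedes")
})

test_that("AUC identities hold against quadrature", {
  pk <- pk_params(); D <- 1.25e6
  auc <- pk_auc(pk, D)
  q1 <- stats::integrate(function(t) pk_single_dose(pk, D, t)$c1, 0, 60,
                         rel.tol = 1e-10, subdivisions = 2000L)$value
  q2 <- stats::integrate(function(t) pk_single_dose(pk, D, t)$c2, 0, 60,
                         rel.tol = 1e-10, subdivisions = 2000L)$value
  expect_equal(q1, auc$auc1, tolerance = 1e-4)
  expect_equal(q2, auc$auc2, tolerance = 1e-4)
  expect_equal(auc$auc2 / auc$auc1, pk$k12 * pk$V1 / (pk$k21 * pk$V2))
})

test_that("total drug amount is non-increasing between doses", {
  pk <- pk_params(); D <- 1.25e6
  times <- seq(0, 14, by = 5e-4)
  prof <- pk_schedule(pk, c(0, 7), c(D, D), times)
  total <- pk$V1 * prof$c1 + pk$V2 * prof$c2
  inter <- times > 0 & times < 7 | times > 7
  expect_true(all(diff(total)[diff(times) > 0 & inter[-1L]] <= 1e-9 * max(total)))
})

test_that("the kill term gates on the threshold and is linear in its drivers", {
  pd <- pd_params(k_eff = 2e-4, c2_thr = 50)
  expect_equal(kill_rate(100, 49.9, pd), 0)   # below threshold: no effect
  expect_equal(kill_rate(100, 50, pd), 0)     # continuous at the threshold
  expect_equal(kill_rate(100, 70, pd), 2e-4 * 20 * 100)
  expect_equal(kill_rate(100, 70, pd_params(0, 50)), 0)
})

test_that("treated simulator reduces to untreated when the drug cannot act", {
  g <- gompertz_params(10, 1e6, 5)
  times <- twice_weekly(10)
  prof <- pk_schedule(pk_params(), c(7, 14), 1.25e6, range(times))
  untr <- gompertz_closed_form(g, times)
  expect_equal(simulate_treated(g, pd_params(0, 0), prof, times), untr,
               tolerance = 1e-12)
  # threshold above the peak concentration: the gate never opens
  peak <- max(pk_schedule(pk_params(), c(7, 14), 1.25e6,
                          seq(0, 31.5, by = 1e-3))$c2)
  expect_equal(
    simulate_treated(g, pd_params(5e-3, peak * 1.01), prof, times), untr,
    tolerance = 1e-12)
})

test_that("log-space closed form agrees with direct ODE integration", {
  times <- twice_weekly(12)
  set.seed(31)
  for (i in 1:4) {
    g <- gompertz_params(runif(1, 4, 30), 1e6, runif(1, 2, 15))
    keff <- 10^runif(1, -4, -2.5)
    prof <- pk_schedule(pk_params(), c(10.5, 17.5, 24.5), 1.25e6,
                        range(times))
    ana <- simulate_treated(g, pd_params(keff, 0), prof, times)
    ode <- simulate_treated(g, pd_params(keff, 0), prof, times,
                            method = "ode")
    expect_equal(ana, ode, tolerance = 1e-6)
  }
  # positive threshold engages the numeric quadrature path
  g <- gompertz_params(8, 1e6, 5)
  prof <- pk_schedule(pk_params(), c(10.5, 17.5), 1.25e6, range(times))
  ana <- simulate_treated(g, pd_params(3e-3, 100), prof, times)
  ode <- simulate_treated(g, pd_params(3e-3, 100), prof, times,
                          method = "ode")
  expect_equal(ana, ode, tolerance = 1e-5)
})

test_that("treatment can only shrink the tumor relative to no treatment", {
  times <- seq(0, 42, by = 0.5)
  set.seed(32)
  for (i in 1:6) {
    g <- gompertz_params(runif(1, 4, 40), 1e6, runif(1, 1, 10))
    prof <- pk_schedule(pk_params(), seq(7, 35, by = 7), 2.5e6, range(times))
    treated <- simulate_treated(g, pd_params(10^runif(1, -5, -2), 0),
                                prof, times)
    expect_true(all(treated <= gompertz_closed_form(g, times) + 1e-9))
  }
})

test_that("one isolated dose removes k_eff * AUC2 in log volume", {
  # slow growth makes the exponential memory factor ~ 1 over the dose
  g <- gompertz_params(200, 1e8, 5)
  keff <- 1e-4; D <- 1.25e6
  prof <- pk_schedule(pk_params(), 7, D, c(0, 20))
  t_eval <- 14  # a week later: the dose has fully cleared
  treated <- simulate_treated(g, pd_params(keff, 0), prof, t_eval)
  untr <- gompertz_closed_form(g, t_eval)
  logkill <- log(untr) - log(treated)
  expect_equal(logkill, keff * pk_auc(pk_params(), D)$auc2, tolerance = 5e-3)
})
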