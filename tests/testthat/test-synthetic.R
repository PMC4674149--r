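test_that("identical seeds reproduce cohorts; different seeds differ", {
  d <- cohort_design(n_untreated = 2L, n_per_treated_arm = 1L, seed = 9L)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1, c2)
  d2 <- d; d2$seed <- 10L
  expect_false(identical(generate_cohort(d2)$measurements, c1$measurements))
})

test_that("degenerate designs behave as specified", {
  # no within-mouse scatter: the three tumors share the mouse doubling time
  d <- cohort_design(within_mouse_sd = 0, seed = 1L)
  set.seed(1)
  p <- sample_mouse_params(d)
  expect_equal(p$tau_g, rep(p$tau_mouse, 3L))

  # all mass on the fast component: every mouse draws from it
  df <- cohort_design(fast_weight = 1, within_mouse_sd = 0, seed = 1L)
  set.seed(2)
  taus <- replicate(40, sample_mouse_params(df)$tau_mouse)
  expect_true(all(abs(taus - df$tau_fast_mean) < 5 * df$tau_fast_sd))
  expect_lt(abs(mean(taus) - df$tau_fast_mean), 2)

  # impossible truncation (mass entirely below the floor) raises after
  # bounded retries
  dbad <- cohort_design(tau_fast_mean = 0.5, tau_fast_sd = 1e-8,
                        fast_weight = 1, seed = 1L)
  set.seed(3)
  expect_error(sample_mouse_params(dbad), "truncated draw")
})

test_that("noiseless measurements reconstruct the simulated volumes exactly", {
  d <- cohort_design(n_untreated = 2L, n_per_treated_arm = 0L,
                     read_noise_sdlog = 0, seed = 5L)
  cohort <- generate_cohort(d)
  for (mid in unique(cohort$measurements$mouse_id)) {
    for (tid in 1:3) {
      rec <- cohort$measurements[cohort$measurements$mouse_id == mid &
                                   cohort$measurements$tumor_id == tid, ]
      s <- build_series(rec)
      tr <- cohort$truth[cohort$truth$mouse_id == mid &
                           cohort$truth$tumor_id == tid, ]
      g <- gompertz_params(tr$true_tau_g, 1e6, s$volumes[1L])
      expect_equal(s$volumes, gompertz_closed_form(g, s$days),
                   tolerance = 1e-12)
    }
  }
})

test_that("onset and sacrifice rules bound the emitted series", {
  d <- cohort_design(seed = 6L)
  cohort <- generate_cohort(d)
  meas <- cohort$measurements
  # no tumor is followed beyond one observation past the 10 mm threshold
  for (mid in unique(meas$mouse_id)) {
    rec <- meas[meas$mouse_id == mid, ]
    days <- sort(unique(rec$day))
    if (length(days) < 2L) next
    before_last <- rec[rec$day < max(days), ]
    diam <- sqrt(apply(before_last[c("len1_mm", "len2_mm", "len3_mm")], 1L,
                       median) *
                 apply(before_last[c("wid1_mm", "wid2_mm", "wid3_mm")], 1L,
                       median))
    # measured diameters carry 5% read noise; allow that on the threshold
    expect_true(all(diam < d$sacrifice_diameter * 1.25))
  }
  # doses begin at the recorded onset and never after follow-up ends
  tr <- cohort$truth
  for (mid in unique(cohort$doses$mouse_id)) {
    dd <- cohort$doses$day[cohort$doses$mouse_id == mid]
    onset <- unique(tr$treatment_start_day[tr$mouse_id == mid])
    expect_equal(min(dd), onset)
    expect_lte(max(dd), unique(tr$last_day[tr$mouse_id == mid]))
    expect_true(all(diff(sort(dd)) == d$dose_interval))
  }
})

test_that("the truth table is complete for every emitted tumor", {
  cohort <- generate_cohort(cohort_design(seed = 8L))
  keys_m <- unique(cohort$measurements[c("mouse_id", "tumor_id")])
  keys_t <- cohort$truth[c("mouse_id", "tumor_id")]
  expect_equal(nrow(merge(keys_m, keys_t)), nrow(keys_m))
  expect_true(all(cohort$truth$true_tau_g > 0))
  treated <- cohort$truth$arm != "DMSO"
  onset_known <- !is.na(cohort$truth$treatment_start_day)
  expect_true(all(!is.na(cohort$truth$true_k_eff[treated])))
  expect_true(all(is.na(cohort$truth$true_k_eff[!treated])))
  expect_true(all(onset_known[treated]))  # every treated mouse reached 3 mm
})

test_that("decoupling the kill law from growth centres the rank correlation at zero", {
  d0 <- cohort_design(n_untreated = 0L, keff_gamma = 0, keff_c = 7.6e-4 / 19,
                      seed = 60L)
  rho <- spearman_structure_check(d0, n_reps = 10L, use_truth = TRUE)
  expect_lt(abs(median(rho)), 0.25)
  # the default inverse coupling makes the generative correlation strongly
  # negative
  d1 <- cohort_design(n_untreated = 0L, seed = 61L)
  rho1 <- spearman_structure_check(d1, n_reps = 10L, use_truth = TRUE)
  expect_lt(median(rho1), -0.5)
})
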