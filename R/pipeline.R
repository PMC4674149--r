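#' Fit every tumor of a cohort
#'
#' Runs the per-tumor estimation pipeline over a measurement table:
#' assembles each tumor's volume series (median-of-three reads,
#' ellipsoid volume), takes the treatment onset from the dose table
#' (first dose day of the mouse), estimates the doubling time from the
#' pre-treatment observations, and for treated tumors estimates the
#' kill rate from the post-onset observations with doses resolved to ng
#' through the recorded body weights. Tumors with insufficient
#' pre-treatment data are retained with `NA` estimates and
#' `excluded = TRUE`.
#'
#' @param measurements Measurement `data.frame`
#'   (see [read_measurements()]).
#' @param doses Dose `data.frame` (`mouse_id,day,dose_mg_per_kg`), or
#'   `NULL` for a fully untreated cohort.
#' @param cfg A [study_config()].
#' @param model `"gompertz"` (default) or `"exponential"` for the
#'   growth fit.
#' @return A cohort `data.frame` with one row per tumor: `mouse_id,
#'   tumor_id, arm, tau_g, k_eff, nmse, nmse_keff, n_pre, n_post,
#'   excluded, tau_at_bound, keff_at_bound`.
#' @export
fit_cohort <- function(measurements, doses = NULL, cfg = study_config(),
                       model = c("gompertz", "exponential")) {
  model <- match.arg(model)
  stopifnot(nrow(measurements) >= 1L)
  validate_measurements(measurements)
  keys <- unique(measurements[c("mouse_id", "tumor_id")])
  keys <- keys[order(keys$mouse_id, keys$tumor_id), ]
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    mid <- keys$mouse_id[i]; tid <- keys$tumor_id[i]
    rec <- measurements[measurements$mouse_id == mid &
                          measurements$tumor_id == tid, ]
    mdoses <- if (is.null(doses)) NULL else doses[doses$mouse_id == mid, ]
    onset <- if (!is.null(mdoses) && nrow(mdoses) > 0L) min(mdoses$day)
             else NULL
    series <- build_series(rec, treatment_start_day = onset)
    arm <- if (is.null(onset)) {
      "DMSO"
    } else {
      lev <- mdoses$dose_mg_per_kg[which.min(mdoses$day)]
      nm <- names(ARM_DOSES_MG_KG)[match(lev, ARM_DOSES_MG_KG)]
      if (is.na(nm)) sprintf("5FU-%g", lev) else nm
    }
    gf <- if (model == "gompertz") fit_tau_g(series, cfg)
          else fit_exponential(series, cfg)
    row <- data.frame(
      mouse_id = mid, tumor_id = tid, arm = arm,
      tau_g = NA_real_, k_eff = NA_real_,
      nmse = NA_real_, nmse_keff = NA_real_,
      n_pre = gf$n_obs, n_post = 0L,
      excluded = is_excluded(gf),
      tau_at_bound = FALSE, keff_at_bound = FALSE,
      stringsAsFactors = FALSE
    )
    if (!is_excluded(gf)) {
      row$tau_g <- unname(gf$estimate["tau_g"])
      row$nmse <- gf$nmse_percent
      row$tau_at_bound <- gf$at_bound
      if (!is.null(onset)) {
        weights <- rec[c("day", "weight_g")]
        dose_ng <- vapply(seq_len(nrow(mdoses)), function(k) {
          resolve_dose_ng(mdoses$dose_mg_per_kg[k], mdoses$day[k], weights)
        }, numeric(1L))
        o <- order(mdoses$day)
        kf <- tryCatch(
          fit_keff(series, row$tau_g, mdoses$day[o], dose_ng[o], cfg),
          error = function(e) NULL
        )
        if (!is.null(kf) && !is_excluded(kf)) {
          row$k_eff <- unname(kf$estimate["k_eff"])
          row$nmse_keff <- kf$nmse_percent
          row$n_post <- kf$n_obs
          row$keff_at_bound <- kf$at_bound
        }
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

write_manifest <- function(out_dir, command, inputs, seed = NULL) {
  manifest <- list(
    command = command,
    package = "tumorpkpd",
    version = as.character(utils::packageVersion("tumorpkpd")),
    inputs = inputs,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Simulate a cohort to disk
#'
#' Writes `measurements.csv`, `doses.csv`, `truth.csv` and a run
#' manifest to `out_dir`. Re-running with the same design and seed
#' reproduces the files exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param design A [cohort_design()]; `seed` overrides its seed when
#'   given.
#' @param seed Optional integer seed.
#' @return Invisibly, the list from [generate_cohort()].
#' @export
run_simulate <- function(out_dir, design = cohort_design(), seed = NULL) {
  if (!is.null(seed)) design$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(design)
  write_measurements(cohort$measurements,
                     file.path(out_dir, "measurements.csv"))
  write_doses(cohort$doses, file.path(out_dir, "doses.csv"))
  utils::write.csv(format_numeric_df(cohort$truth),
                   file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "simulate", inputs = list(), seed = design$seed)
  invisible(cohort)
}

#' Fit a cohort from files
#'
#' Reads measurement and dose tables, runs [fit_cohort()], and writes
#' the per-tumor estimate table (`cohort_fits.csv`), a JSON version,
#' and the exclusion log.
#'
#' @param measurements_path,doses_path Input CSV paths (`doses_path`
#'   may be `NULL`).
#' @param out_dir Output directory.
#' @param config_path Optional YAML configuration
#'   (see [read_study_config()]).
#' @return Invisibly, the cohort fit `data.frame`.
#' @export
run_fit <- function(measurements_path, doses_path = NULL, out_dir,
                    config_path = NULL) {
  cfg <- if (is.null(config_path)) study_config()
         else read_study_config(config_path)
  meas <- read_measurements(measurements_path)
  doses <- if (is.null(doses_path)) NULL else read_doses(doses_path)
  fits <- fit_cohort(meas, doses, cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fits, file.path(out_dir, "cohort_fits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(fits, file.path(out_dir, "cohort_fits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  excl <- fits[fits$excluded, c("mouse_id", "tumor_id", "n_pre")]
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "fit",
                 inputs = list(measurements = measurements_path,
                               doses = doses_path, config = config_path))
  invisible(fits)
}

#' Reference cohort statistics recomputed from the packaged tables
#'
#' Recomputes the headline cohort statistics from the packaged study
#' tables: the within/between-mouse variance decomposition of the 24
#' untreated doubling times, their mean and standard error, and the
#' Spearman correlation between doubling time and kill rate over the
#' 39 treated tumors. Each statistic is paired with the value reported
#' for the original study and a pass flag at the reporting precision
#' (one unit in the last reported digit).
#'
#' @return A `data.frame` with columns `statistic, computed, reference,
#'   tolerance, pass`.
#' @export
reproduce_statistics <- function() {
  tabs <- load_study_tables()
  vc <- variance_components(tabs$untreated$tau_g, tabs$untreated$mouse_id)
  sm <- summarize_values(tabs$untreated$tau_g)
  sp <- spearman(tabs$treated$tau_g, tabs$treated$k_eff)
  ref <- data.frame(
    statistic = c("msw_tau_untreated", "msb_tau_untreated",
                  "f_pvalue_tau_untreated", "mean_tau_untreated",
                  "se_tau_untreated", "spearman_tau_keff"),
    computed = c(vc$msw, vc$msb, vc$p_value, sm$mean, sm$se, sp$rho),
    reference = c(118.0, 282.9, 0.07, 18.5, 2.65, -0.727),
    tolerance = c(0.1, 0.1, 0.01, 0.1, 0.01, 0.001),
    stringsAsFactors = FALSE
  )
  ref$pass <- abs(ref$computed - ref$reference) <= ref$tolerance
  ref
}

#' Reproduce the reference statistics to disk
#'
#' Runs [reproduce_statistics()], prints the comparison, and writes it
#' as CSV and JSON with a manifest.
#'
#' @param out_dir Output directory.
#' @return Invisibly, the comparison `data.frame`.
#' @export
run_reproduce <- function(out_dir) {
  rep <- reproduce_statistics()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep, file.path(out_dir, "reproduce.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, file.path(out_dir, "reproduce.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "reproduce", inputs = list())
  print(rep)
  invisible(rep)
}
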