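#' Study arm labels
#'
#' The three experimental arms: vehicle control (`DMSO`) and weekly
#' intraperitoneal 5-fluorouracil at 50 or 100 mg/kg.
#' @export
STUDY_ARMS <- c("DMSO", "5FU-50", "5FU-100")

#' Dose levels (mg/kg) of the two treatment arms
#' @export
ARM_DOSES_MG_KG <- c(`5FU-50` = 50, `5FU-100` = 100)

measurement_columns <- c(
  "mouse_id", "tumor_id", "day",
  "len1_mm", "len2_mm", "len3_mm",
  "wid1_mm", "wid2_mm", "wid3_mm", "weight_g"
)

#' Read a caliper measurement table
#'
#' Reads a long-format CSV of caliper observation events. Each row is one
#' observation of one tumor on one day and carries the triplicate length
#' and width reads (mm) plus the mouse body weight (g; may be `NA` on
#' tumor-only days). Day is measured in days from the first visible tumor
#' of the series and may be fractional.
#'
#' @param path Path to a CSV file with columns
#'   `mouse_id,tumor_id,day,len1_mm,len2_mm,len3_mm,wid1_mm,wid2_mm,wid3_mm,weight_g`.
#' @return A `data.frame` with those columns, one row per
#'   (mouse, tumor, day). Rows with non-positive reads or negative days
#'   abort with row-level diagnostics.
#' @seealso [write_measurements()], [build_series()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing) > 0L) {
    stop("measurement file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  df <- df[measurement_columns]
  num_cols <- setdiff(measurement_columns, c("mouse_id", "tumor_id"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad) > 0L) {
        stop("non-numeric values in column '", cl, "' at data row(s) ",
             paste(utils::head(bad, 10L), collapse = ", "))
      }
      df[[cl]] <- vn
    }
  }
  validate_measurements(df)
  df
}

validate_measurements <- function(df) {
  read_cols <- c("len1_mm", "len2_mm", "len3_mm", "wid1_mm", "wid2_mm", "wid3_mm")
  reads <- as.matrix(df[read_cols])
  bad <- which(apply(reads, 1L, function(r) any(is.na(r) | r <= 0)))
  if (length(bad) > 0L) {
    stop("non-positive or missing caliper reads at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (any(is.na(df$day) | df$day < 0)) {
    stop("negative or missing day at data row(s): ",
         paste(utils::head(which(is.na(df$day) | df$day < 0), 10L), collapse = ", "))
  }
  key <- paste(df$mouse_id, df$tumor_id, df$day)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse, tumor, day) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  }
  invisible(df)
}

#' Write a caliper measurement table
#'
#' Inverse of [read_measurements()]; a read/write round trip preserves
#' every field to full precision.
#' @param df Measurement `data.frame` in the [read_measurements()] schema.
#' @param path Output CSV path.
#' @export
write_measurements <- function(df, path) {
  stopifnot(all(measurement_columns %in% names(df)))
  utils::write.csv(format_numeric_df(df[measurement_columns]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision text rendering so CSV round trips are exact
format_numeric_df <- function(df) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) {
      df[[cl]] <- vapply(df[[cl]], function(x) {
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1L))
    }
  }
  df
}

#' Read a dose-event table
#'
#' @param path CSV with columns `mouse_id,day,dose_mg_per_kg`.
#' @return `data.frame` of dose events; all doses must be positive.
#' @export
read_doses <- function(path) {
  if (!file.exists(path)) stop("dose file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "day", "dose_mg_per_kg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("dose file lacks required columns: ", paste(missing, collapse = ", "))
  }
  if (any(is.na(df$dose_mg_per_kg) | df$dose_mg_per_kg <= 0)) {
    stop("non-positive dose at data row(s): ",
         paste(which(is.na(df$dose_mg_per_kg) | df$dose_mg_per_kg <= 0), collapse = ", "))
  }
  df[need]
}

#' Write a dose-event table
#' @param df Dose `data.frame` (`mouse_id,day,dose_mg_per_kg`).
#' @param path Output CSV path.
#' @export
write_doses <- function(df, path) {
  stopifnot(all(c("mouse_id", "day", "dose_mg_per_kg") %in% names(df)))
  utils::write.csv(format_numeric_df(df[c("mouse_id", "day", "dose_mg_per_kg")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve a mg/kg dose to an absolute amount in ng
#'
#' Body weights are recorded biweekly, so the weight used is the one
#' recorded nearest to the dose day; when two records are equidistant the
#' earlier one is used.
#'
#' @param dose_mg_per_kg Dose level in mg per kg body weight.
#' @param dose_day Day of administration.
#' @param weights `data.frame` with columns `day` and `weight_g` for the
#'   dosed mouse (rows with `NA` weight are ignored).
#' @return Absolute dose in ng: `dose_mg_per_kg * weight_kg * 1e6`.
#' @examples
#' w <- data.frame(day = 0, weight_g = 25)
#' resolve_dose_ng(50, 0, w)   # 1.25e6 ng
#' resolve_dose_ng(100, 0, w)  # 2.5e6 ng
#' @export
resolve_dose_ng <- function(dose_mg_per_kg, dose_day, weights) {
  stopifnot(is.numeric(dose_mg_per_kg), dose_mg_per_kg > 0)
  w <- weights[!is.na(weights$weight_g), , drop = FALSE]
  if (nrow(w) == 0L) stop("cannot resolve dose: no recorded body weights")
  dist <- abs(w$day - dose_day)
  # ties broken toward the earlier day: order by (distance, day)
  i <- order(dist, w$day)[1L]
  dose_mg_per_kg * (w$weight_g[i] / 1000) * 1e6
}

#' Packaged per-tumor estimate tables from the mouse study
#'
#' Returns the two cohort tables of per-tumor estimates published for the
#' original de novo carcinogenesis study: doubling times for the 8
#' untreated (DMSO) mice (3 tumors each, 24 values) and doubling-time /
#' kill-rate pairs for the 39 estimable tumors of the 16 treated mice.
#'
#' @return A list with elements `untreated` and `treated`, each a
#'   cohort `data.frame` with columns `mouse_id`, `tumor_id`, `arm`,
#'   `tau_g` (days), `k_eff` (ml/(day*ng), `NA` for untreated) and
#'   `nmse` (`NA`; not published per tumor).
#' @examples
#' tabs <- load_study_tables()
#' nrow(tabs$untreated)  # 24
#' nrow(tabs$treated)    # 39
#' @export
load_study_tables <- function() {
  f1 <- system.file("extdata", "untreated_tau_g.csv", package = "tumorpkpd",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "treated_tau_keff.csv", package = "tumorpkpd",
                    mustWork = TRUE)
  u <- utils::read.csv(f1, stringsAsFactors = FALSE)
  t <- utils::read.csv(f2, stringsAsFactors = FALSE)
  untreated <- data.frame(
    mouse_id = u$mouse_id, tumor_id = u$tumor_id, arm = "DMSO",
    tau_g = u$tau_g_days, k_eff = NA_real_, nmse = NA_real_,
    stringsAsFactors = FALSE
  )
  treated <- data.frame(
    mouse_id = t$mouse_id, tumor_id = t$tumor_id, arm = t$arm,
    tau_g = t$tau_g_days, k_eff = t$k_eff_ml_per_day_ng, nmse = NA_real_,
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(untreated) == 24L, nrow(treated) == 39L,
            all(treated$arm %in% STUDY_ARMS))
  list(untreated = untreated, treated = treated)
}

#' Study configuration
#'
#' Collects the fixed model constants and solver/fitting settings used
#' throughout the pipeline.
#'
#' @param theta_g Gompertz plateau volume in mm^3 (default `1e6`,
#'   i.e. about 1e12 cells at 1e6 cells/mm^3). Never estimated; results
#'   are insensitive to it while observed volumes stay far below it.
#' @param c2_thr Therapeutic threshold concentration at the tumor site,
#'   ng/ml. Below this the drug has no antitumor effect. Default 0.
#' @param pk [pk_params()] object with the two-compartment constants.
#' @param solver List of ODE tolerances: `rtol`, `atol` (defaults 1e-8).
#' @param fit List of fitting settings: `tau_bounds` (days, default
#'   `c(1, 200)`), `keff_bounds` (ml/(day*ng), default `c(0, 1e-2)`),
#'   `multistarts` (default 8 log-spaced initializations), `min_obs`
#'   (minimum usable observations per fit, default 3).
#' @return An object of class `study_config`.
#' @export
study_config <- function(theta_g = 1e6,
                         c2_thr = 0,
                         pk = pk_params(),
                         solver = list(rtol = 1e-8, atol = 1e-8),
                         fit = list()) {
  stopifnot(theta_g > 0, c2_thr >= 0,
            solver$rtol > 0, solver$atol > 0)
  fdef <- list(tau_bounds = c(1, 200), keff_bounds = c(0, 1e-2),
               multistarts = 8L, min_obs = 3L)
  fdef[names(fit)] <- fit
  stopifnot(fdef$tau_bounds[1] > 0, diff(fdef$tau_bounds) > 0,
            fdef$keff_bounds[1] >= 0, diff(fdef$keff_bounds) > 0,
            fdef$multistarts >= 1L, fdef$min_obs >= 2L)
  structure(list(theta_g = theta_g, c2_thr = c2_thr, pk = pk,
                 solver = solver, fit = fdef),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys mirror [study_config()]: `theta_g_mm3`,
#' `c2_thr_ng_ml`, `pk` (`k10,k12,k21,V1,V2`), `solver` (`rtol,atol`),
#' `fit` (`tau_bounds,keff_bounds,multistarts,min_obs`). Missing keys
#' fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  # YAML 1.1 only recognizes scientific notation with a signed exponent;
  # coerce scalar fields so '2.0e6' style values still parse
  num <- function(x) if (is.null(x)) x else as.numeric(x)
  y$theta_g_mm3 <- num(y$theta_g_mm3)
  y$c2_thr_ng_ml <- num(y$c2_thr_ng_ml)
  if (!is.null(y$pk)) y$pk <- lapply(y$pk, as.numeric)
  if (!is.null(y$solver)) y$solver <- lapply(y$solver, as.numeric)
  pk <- if (is.null(y$pk)) pk_params() else do.call(pk_params, y$pk)
  solver <- list(rtol = 1e-8, atol = 1e-8)
  if (!is.null(y$solver)) solver[names(y$solver)] <- y$solver
  fit <- if (is.null(y$fit)) list() else lapply(y$fit, unlist)
  study_config(
    theta_g = if (is.null(y$theta_g_mm3)) 1e6 else y$theta_g_mm3,
    c2_thr = if (is.null(y$c2_thr_ng_ml)) 0 else y$c2_thr_ng_ml,
    pk = pk, solver = solver, fit = fit
  )
}
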