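#' Median of three caliper reads
#'
#' Each length and width is measured three times; the middle order
#' statistic is used downstream to suppress gross read errors.
#'
#' @param reads Numeric vector of exactly 3 positive reads (mm).
#' @return The middle order statistic.
#' @examples
#' median_of_three(c(3, 4, 5))  # 4
#' median_of_three(c(5, 3, 4))  # 4
#' @export
median_of_three <- function(reads) {
  if (length(reads) != 3L) {
    stop("median_of_three expects exactly 3 reads, got ", length(reads))
  }
  if (any(is.na(reads) | reads <= 0)) stop("caliper reads must be positive")
  sort(reads)[2L]
}

#' Ellipsoid tumor volume from caliper length and width
#'
#' The tumor is approximated as an ellipsoid, giving
#' `V = pi/6 * (x*y)^(3/2)` with `x`, `y` the caliper length and width
#' in mm. The formula is symmetric in its arguments and scales as the
#' cube of the linear dimension.
#'
#' @param x,y Length and width in mm (positive; vectorized).
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(1, 1)    # pi/6 ~ 0.5236 (1 mm sphere)
#' ellipsoid_volume(10, 10)  # ~523.6 (1 cm sacrifice threshold)
#' @export
ellipsoid_volume <- function(x, y) {
  if (any(is.na(x) | is.na(y) | x <= 0 | y <= 0)) {
    stop("caliper dimensions must be positive")
  }
  pi / 6 * (x * y)^1.5
}

#' Diameter of a sphere with a given volume
#'
#' Inverse of [ellipsoid_volume()] on the sphere diagonal (`x == y`);
#' used for the 3 mm treatment-onset and 10 mm sacrifice rules, which
#' compare the geometric-mean diameter `sqrt(x*y)` against a threshold.
#'
#' @param volume Volume in mm^3.
#' @return Equivalent spherical diameter in mm.
#' @export
sphere_diameter <- function(volume) {
  stopifnot(all(volume >= 0))
  (6 * volume / pi)^(1 / 3)
}

#' Per-tumor volume time series
#'
#' Container for one tumor's derived (day, volume) series. Days are
#' re-based so the first observation is day 0; `treatment_start_day`
#' (on the same re-based clock) is `NULL` for untreated tumors.
#'
#' @param mouse_id,tumor_id Identifiers.
#' @param days Strictly increasing observation days.
#' @param volumes Positive volumes in mm^3, one per day.
#' @param treatment_start_day Optional first-dose day.
#' @return An object of class `tumor_series`.
#' @export
tumor_series <- function(mouse_id, tumor_id, days, volumes,
                         treatment_start_day = NULL) {
  stopifnot(length(days) == length(volumes), length(days) >= 1L)
  if (any(volumes <= 0)) stop("tumor volumes must be positive")
  if (any(diff(days) <= 0)) stop("observation days must be strictly increasing")
  structure(
    list(mouse_id = mouse_id, tumor_id = tumor_id,
         days = as.numeric(days), volumes = as.numeric(volumes),
         treatment_start_day = treatment_start_day),
    class = "tumor_series"
  )
}

#' @export
print.tumor_series <- function(x, ...) {
  cat(sprintf("tumor_series: mouse %s tumor %s, %d observations over %.1f days\n",
              x$mouse_id, x$tumor_id, length(x$days), max(x$days)))
  if (!is.null(x$treatment_start_day)) {
    cat(sprintf("  treatment from day %.1f\n", x$treatment_start_day))
  }
  invisible(x)
}

#' Assemble a tumor series from caliper records
#'
#' Applies the median-of-three rule to the length and width reads
#' separately, converts to volumes with [ellipsoid_volume()], sorts by
#' day and re-bases the clock to the first observation.
#'
#' @param records Measurement `data.frame` rows
#'   (see [read_measurements()]) for a single tumor.
#' @param treatment_start_day Optional first-dose day on the original
#'   (pre-re-basing) clock.
#' @return A [tumor_series()].
#' @export
build_series <- function(records, treatment_start_day = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (length(unique(records$mouse_id)) != 1L ||
      length(unique(records$tumor_id)) != 1L) {
    stop("build_series expects records from a single tumor")
  }
  if (anyDuplicated(records$day)) stop("duplicate observation days")
  o <- order(records$day)
  records <- records[o, , drop = FALSE]
  x <- apply(as.matrix(records[c("len1_mm", "len2_mm", "len3_mm")]), 1L,
             median_of_three)
  y <- apply(as.matrix(records[c("wid1_mm", "wid2_mm", "wid3_mm")]), 1L,
             median_of_three)
  day0 <- records$day[1L]
  tumor_series(
    mouse_id = records$mouse_id[1L], tumor_id = records$tumor_id[1L],
    days = records$day - day0,
    volumes = ellipsoid_volume(x, y),
    treatment_start_day = if (is.null(treatment_start_day)) NULL
                          else treatment_start_day - day0
  )
}
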