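# WBC/RBC enumeration arithmetic.
#
# WBCs are identified in the fluorescence channel (nuclear stain); RBCs are
# the remainder of the bright-field count: n_rbc = n_total - n_wbc, clamped
# at zero.  Concentrations pool counts over the chamber's imaged areas and
# divide by the calibrated analysis volume.

#' Count one imaged area
#'
#' Combines the bright-field and fluorescence detections of one area into
#' `(n_total, n_wbc, n_rbc)`.
#'
#' In the default `"subtraction"` mode, `n_total` is the bright-field
#' detection count, `n_wbc` the fluorescence count, and
#' `n_rbc = max(n_total - n_wbc, 0)`; a fluorescence count exceeding the
#' bright-field count signals a QC problem and raises a clamping warning.
#' In `"matched"` mode WBCs are the fluorescence detections that pair with a
#' bright-field detection within `tol` (via [match_detections()]), RBCs the
#' unmatched bright-field detections, and unmatched fluorescence detections
#' are counted as WBCs and added to the total.
#'
#' @param bf,fl Detection tibbles for the same area.
#' @param mode `"subtraction"` (the instrument's rule) or `"matched"`.
#' @param tol Pairing tolerance (um) for `"matched"` mode.
#' @return A one-row tibble: `n_total`, `n_wbc`, `n_rbc`, `clamped`.
#' @export
#' @examples
#' bf <- tibble::tibble(cx_um = 1:12 * 10, cy_um = 50, radius_um = 5,
#'                      score = 1, modality = "bright_field")
#' fl <- bf[1:4, ]
#' count_area(bf, fl)   # 12 total, 4 WBC, 8 RBC
count_area <- function(bf, fl, mode = c("subtraction", "matched"), tol = 3) {
  mode <- match.arg(mode)
  if (mode == "subtraction") {
    n_total <- nrow(bf)
    n_wbc <- nrow(fl)
    clamped <- n_wbc > n_total
    if (clamped) {
      warn(sprintf(
        "fluorescence count (%d) exceeds bright-field count (%d); RBC count clamped at 0",
        n_wbc, n_total), class = "csfcount_clamp_warning")
    }
    n_rbc <- max(n_total - n_wbc, 0L)
  } else {
    m <- match_detections(bf, fl, tol)
    n_wbc <- nrow(m$pairs) + length(m$unmatched_b)
    n_rbc <- length(m$unmatched_a)
    n_total <- nrow(bf) + length(m$unmatched_b)
    clamped <- FALSE
  }
  tibble(n_total = as.integer(n_total), n_wbc = as.integer(n_wbc),
         n_rbc = as.integer(n_rbc), clamped = clamped)
}

#' Concentrations from per-area counts
#'
#' Pools counts over the chamber's imaged areas and divides by the analysis
#' volume: `c = sum(counts) / (analysis_volume in uL)`.  The coefficient of
#' variation across areas (`sd / mean` of per-area counts) is reported per
#' class, `NA` when the mean count is zero.
#'
#' @param per_area A data frame with one row per imaged area and columns
#'   `n_total`, `n_wbc`, `n_rbc` (as produced by [count_area()]).
#' @param chamber A [chamber_spec()]; supplies `analysis_volume` and the
#'   expected number of areas (fewer rows draws a warning, not an error).
#' @return An object of class `count_result`.
#' @export
#' @examples
#' pa <- tibble::tibble(n_total = c(8, 7, 8, 7), n_wbc = c(1, 1, 0, 1))
#' pa$n_rbc <- pa$n_total - pa$n_wbc
#' concentrations(pa, chamber_spec())
concentrations <- function(per_area, chamber = chamber_spec()) {
  stopifnot(inherits(chamber, "chamber_spec"))
  per_area <- as_tibble(per_area)
  if (chamber$analysis_volume <= 0) {
    abort_validation("`analysis_volume` must be > 0", "analysis_volume")
  }
  if (nrow(per_area) < chamber$n_areas) {
    warn(sprintf("counted %d area(s); chamber expects %d",
                 nrow(per_area), chamber$n_areas))
  }
  vol_uL <- chamber$analysis_volume / 1000
  conc <- function(col) sum(per_area[[col]]) / vol_uL
  cv <- function(col) {
    m <- mean(per_area[[col]])
    if (nrow(per_area) < 2 || m == 0) NA_real_ else sd(per_area[[col]]) / m
  }
  structure(
    list(per_area = per_area,
         c_total = conc("n_total"), c_wbc = conc("n_wbc"),
         c_rbc = conc("n_rbc"),
         cv_total = cv("n_total"), cv_wbc = cv("n_wbc"), cv_rbc = cv("n_rbc"),
         analysis_volume = chamber$analysis_volume),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d area(s), %g nL analyzed\n",
              nrow(x$per_area), x$analysis_volume))
  cat(sprintf("  c_total = %.2f, c_wbc = %.2f, c_rbc = %.2f cells/uL\n",
              x$c_total, x$c_wbc, x$c_rbc))
  cat(sprintf("  CV across areas: total %s, wbc %s, rbc %s\n",
              format(round(x$cv_total, 3)), format(round(x$cv_wbc, 3)),
              format(round(x$cv_rbc, 3))))
  invisible(x)
}

#' @export
tidy.count_result <- function(x, ...) {
  dplyr::mutate(x$per_area, area = dplyr::row_number(), .before = 1)
}

#' @export
glance.count_result <- function(x, ...) {
  tibble(c_total = x$c_total, c_wbc = x$c_wbc, c_rbc = x$c_rbc,
         cv_total = x$cv_total, cv_wbc = x$cv_wbc, cv_rbc = x$cv_rbc,
         n_areas = nrow(x$per_area), analysis_volume_nl = x$analysis_volume)
}

#' Poisson counting floor on the CV
#'
#' Counting statistics bound the coefficient of variation of any
#' fixed-volume count from below by `1 / sqrt(N)`, with `N` the expected
#' total count in the analyzed volume.  Useful for judging whether measured
#' between-replicate CVs are dominated by sampling noise.
#'
#' @param expected_total_count Expected number of cells in the analyzed
#'   volume (> 0).
#' @return The CV lower bound (fraction).
#' @export
#' @examples
#' poisson_cv(100)                 # 0.10
#' poisson_cv(5.2 * 0.588)         # lowest tested concentration: ~0.57
poisson_cv <- function(expected_total_count) {
  check_number(expected_total_count, "expected_total_count",
               min = 0, strict_min = TRUE)
  1 / sqrt(expected_total_count)
}
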