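#' Shape-based canal area approximations
#'
#' Closed-form estimates of the canal cross-sectional area from the two
#' linear measurements. Treating the canal as an ellipse with semi-axes
#' IPD/2 and AP/2 gives `pi * (ipd/2) * (ap/2)`; as a triangle with base IPD
#' and height AP gives `ipd * ap / 2`; as the bounding rectangle,
#' `ipd * ap`. The three are exact positive multiples of one another
#' (`ellipse = (pi/4) * rectangle`, `triangle = rectangle / 2`), which is
#' why they share a single Pearson correlation with any reference
#' measurement at a given level.
#'
#' @param ap Anteroposterior diameter, mm (vectorised).
#' @param ipd Interpedicular distance, mm (vectorised, recycled against `ap`).
#' @return Area in mm^2.
#' @name shape_areas
#' @examples
#' ellipse_area(10, 20)   # pi * 10 * 5
#' triangle_area(10, 20)  # 100
#' rectangle_area(10, 20) # 200
NULL

check_positive_lengths <- function(ap, ipd) {
  if (length(ap) == 0L || length(ipd) == 0L) return(invisible(NULL))
  if (any(!is.finite(ap) | ap <= 0)) {
    stop("shape approximation domain error: ap diameter must be positive and finite",
         call. = FALSE)
  }
  if (any(!is.finite(ipd) | ipd <= 0)) {
    stop("shape approximation domain error: interpedicular distance must be positive and finite",
         call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname shape_areas
#' @export
ellipse_area <- function(ap, ipd) {
  check_positive_lengths(ap, ipd)
  pi * (ipd / 2) * (ap / 2)
}

#' @rdname shape_areas
#' @export
triangle_area <- function(ap, ipd) {
  check_positive_lengths(ap, ipd)
  (ipd * ap) / 2
}

#' @rdname shape_areas
#' @export
rectangle_area <- function(ap, ipd) {
  check_positive_lengths(ap, ipd)
  ipd * ap
}

#' Compute all shape approximations for a cohort
#'
#' Applies the three shape models to every record, preserving row order so
#' approximations can be paired positionally with the measured areas. All
#' arithmetic is double precision; display rounding happens only in the
#' report tables.
#'
#' @param cohort A `canal_cohort` (see [as_cohort()]).
#' @return Tibble aligned to `cohort` rows with columns `patient_id`,
#'   `level`, `ellipse_mm2`, `triangle_mm2`, `rectangle_mm2`.
#' @export
approximate_cohort <- function(cohort) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "unspecified")
  tibble::tibble(
    patient_id = cohort$patient_id,
    level = cohort$level,
    ellipse_mm2 = ellipse_area(cohort$ap_diameter_mm, cohort$ipd_mm),
    triangle_mm2 = triangle_area(cohort$ap_diameter_mm, cohort$ipd_mm),
    rectangle_mm2 = rectangle_area(cohort$ap_diameter_mm, cohort$ipd_mm)
  )
}
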