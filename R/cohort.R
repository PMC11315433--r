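#' Cervical disc levels handled by the pipeline
#'
#' The five cervical disc levels at which canal measurements are taken,
#' ordered cranial to caudal. All level columns in the package are factors
#' with these levels, so per-level summaries always come out in anatomical
#' order.
#'
#' @return Character vector `c("C2-3", "C3-4", "C4-5", "C5-6", "C6-7")`.
#' @export
#' @examples
#' cervical_levels()
cervical_levels <- function() {
  c("C2-3", "C3-4", "C4-5", "C5-6", "C6-7")
}

#' Canonicalise level labels
#'
#' Parsing is case-insensitive and whitespace-tolerant; the canonical form
#' ("C2-3", ...) is always what gets stored and written.
#'
#' @param x Character vector of level labels.
#' @return Factor with levels `cervical_levels()`; unknown labels are `NA`.
#' @keywords internal
canonical_level <- function(x) {
  lv <- cervical_levels()
  idx <- match(toupper(trimws(as.character(x))), toupper(lv))
  factor(lv[idx], levels = lv)
}

cohort_columns <- function() {
  c("patient_id", "level", "ap_diameter_mm", "ipd_mm", "measured_area_mm2")
}

#' Build a validated measurement cohort
#'
#' A cohort is a tibble with one row per patient x level observation:
#' `patient_id` (opaque identifier), `level` (one of [cervical_levels()]),
#' `ap_diameter_mm` (anteroposterior canal diameter, mm), `ipd_mm`
#' (interpedicular distance, mm) and `measured_area_mm2` (manually traced
#' canal area, mm^2). Validation is total: either every row passes or a
#' located error is raised; no rows are dropped silently.
#'
#' @param x Data frame with the five cohort columns. Measurement columns may
#'   be character (as read from file); they are converted.
#' @param provenance Free-text tag describing where the records came from
#'   (e.g. `"synthetic:seed=17"`), kept as the `"provenance"` attribute.
#' @return A `canal_cohort` tibble (row order preserved).
#' @export
#' @examples
#' as_cohort(tibble::tibble(
#'   patient_id = "P1", level = "C2-3",
#'   ap_diameter_mm = 12, ipd_mm = 25, measured_area_mm2 = 250
#' ))
as_cohort <- function(x, provenance = "unspecified") {
  x <- tibble::as_tibble(x)
  missing <- setdiff(cohort_columns(), names(x))
  if (length(missing) > 0L) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[cohort_columns()]
  x$patient_id <- as.character(x$patient_id)

  raw_level <- x$level
  x$level <- canonical_level(raw_level)
  if (anyNA(x$level)) {
    bad <- which(is.na(x$level))[1L]
    stop(sprintf(
      "cohort validation error: row %d, field level: unknown level label '%s' (expected one of %s)",
      bad, as.character(raw_level)[bad], paste(cervical_levels(), collapse = ", ")),
      call. = FALSE)
  }

  for (col in c("ap_diameter_mm", "ipd_mm", "measured_area_mm2")) {
    raw <- x[[col]]
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1L]
      stop(sprintf(
        "cohort validation error: row %d, field %s: non-numeric value '%s'",
        bad, col, as.character(raw)[bad]), call. = FALSE)
    }
    if (any(!is.finite(val) | val <= 0)) {
      bad <- which(!is.finite(val) | val <= 0)[1L]
      stop(sprintf(
        "cohort validation error: row %d, field %s: value %s is not a positive finite measurement",
        bad, col, format(val[bad])), call. = FALSE)
    }
    x[[col]] <- val
  }

  key <- paste(x$patient_id, as.character(x$level), sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf(
      "cohort validation error: row %d: duplicate (patient_id, level) pair ('%s', %s)",
      bad, x$patient_id[bad], as.character(x$level)[bad]), call. = FALSE)
  }

  attr(x, "provenance") <- as.character(provenance)
  class(x) <- c("canal_cohort", setdiff(class(x), "canal_cohort"))
  x
}

#' @export
print.canal_cohort <- function(x, ...) {
  cat(sprintf("# Canal measurement cohort: %d records, %d patients (provenance: %s)\n",
              nrow(x), length(unique(x$patient_id)),
              attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

#' Read a measurement cohort from CSV
#'
#' The file must carry the header
#' `patient_id,level,ap_diameter_mm,ipd_mm,measured_area_mm2` (UTF-8,
#' decimal point, no thousands separators). Every row is validated through
#' [as_cohort()]; errors name the offending row and field.
#'
#' @param path Path to a CSV file.
#' @param provenance Provenance tag; defaults to `"file:<path>"`.
#' @return A `canal_cohort` tibble; a header-only file yields an empty cohort.
#' @export
read_cohort <- function(path, provenance = paste0("file:", path)) {
  if (!file.exists(path)) {
    stop("cohort I/O error: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  as_cohort(df, provenance = provenance)
}

#' Write a measurement cohort to CSV
#'
#' Numeric fields are serialised with 17 significant digits so that
#' `read_cohort(write_cohort(x, p))` reproduces every stored double exactly;
#' level labels are written in canonical form.
#'
#' @param cohort A `canal_cohort` (or coercible data frame).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "unspecified")
  out <- data.frame(
    patient_id = cohort$patient_id,
    level = as.character(cohort$level),
    ap_diameter_mm = formatC(cohort$ap_diameter_mm, digits = 17, format = "g"),
    ipd_mm = formatC(cohort$ipd_mm, digits = 17, format = "g"),
    measured_area_mm2 = formatC(cohort$measured_area_mm2, digits = 17, format = "g"),
    check.names = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cohort I/O error: cannot write '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
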