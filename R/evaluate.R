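#' Paired mean difference
#'
#' Mean and sample SD (n - 1 denominator) of the per-record difference
#' `approx - measured`. The sign convention is approximation minus manual,
#' so a model that underestimates the canal area has a negative mean
#' difference.
#'
#' @param approx,measured Positionally paired area vectors (equal length >= 1).
#' @return Named list with `mean` and `sd` (mm^2); `sd` is `NA` for a single
#'   pair.
#' @export
mean_difference <- function(approx, measured) {
  if (length(approx) != length(measured) || length(approx) < 1L) {
    stop("evaluation pairing error: approx and measured must be non-empty vectors of equal length",
         call. = FALSE)
  }
  d <- approx - measured
  list(mean = mean(d), sd = if (length(d) >= 2L) stats::sd(d) else NA_real_)
}

#' Percent error of an approximation
#'
#' Three readings of "percent error" are offered:
#' \describe{
#'   \item{`of_means`}{`100 * (mean(approx) - mean(measured)) / mean(measured)`
#'     — the relative bias of the level mean; the default, and the
#'     definition under which the published per-shape percent-error table is
#'     exactly recomputable from the level means.}
#'   \item{`mean_of_ratios`}{mean of the per-record signed
#'     `100 * (a - m) / m`.}
#'   \item{`mean_abs_ratio`}{mean of the per-record `100 * |a - m| / m` —
#'     a mean absolute percent error; the only reading consistent with
#'     quoting a 15-19% "percent error" for a model whose mean difference is
#'     essentially zero, as happens for the second-order approximations.}
#' }
#'
#' @inheritParams mean_difference
#' @param mode One of `"of_means"`, `"mean_of_ratios"`, `"mean_abs_ratio"`.
#' @return Percent error (a percentage, e.g. `-8.26`).
#' @export
percent_error <- function(approx, measured,
                          mode = c("of_means", "mean_of_ratios", "mean_abs_ratio")) {
  mode <- match.arg(mode)
  if (length(approx) != length(measured) || length(approx) < 1L) {
    stop("evaluation pairing error: approx and measured must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(measured) | measured <= 0)) {
    stop("evaluation domain error: measured areas must be positive", call. = FALSE)
  }
  switch(mode,
    of_means = 100 * (mean(approx) - mean(measured)) / mean(measured),
    mean_of_ratios = mean(100 * (approx - measured) / measured),
    mean_abs_ratio = mean(100 * abs(approx - measured) / measured)
  )
}

#' Pearson correlation between approximation and measurement
#'
#' Thin wrapper around the sample Pearson correlation with the
#' preconditions the agreement tables need (at least 3 pairs, non-degenerate
#' variance). Because all shape approximations are positive multiples of
#' AP x IPD, they share one correlation per level.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return Sample correlation coefficient.
#' @seealso [correlation_strength()] for the weak/moderate/strong banding.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("evaluation pairing error: pearson_r needs paired vectors of length >= 3",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("evaluation error: correlation undefined for zero-variance input",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Qualitative correlation band
#'
#' Classifies |r| as `"weak"` (below 0.4), `"moderate"` (0.4 up to 0.7) or
#' `"strong"` (0.7 and above).
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' correlation_strength(c(0.3, 0.541, 0.700))
correlation_strength <- function(r) {
  a <- abs(r)
  if (any(!is.finite(a) | a > 1)) {
    stop("correlation_strength: r must lie in [-1, 1]", call. = FALSE)
  }
  ifelse(a >= 0.7, "strong", ifelse(a >= 0.4, "moderate", "weak"))
}

#' Paired sample t-test
#'
#' Two-sided paired t-test of `x - y`, with the degenerate cases the
#' agreement pipeline can produce handled explicitly: identical pairs give
#' `t = 0, p = 1`; a constant non-zero difference gives `t = +/-Inf, p = 0`.
#' Also returns the 95% confidence interval of the mean difference.
#'
#' @param x,y Paired numeric vectors, equal length >= 2.
#' @param conf_level Confidence level for the mean-difference CI.
#' @return Named list: `t`, `df`, `p`, `n`, `mean_diff`, `sd_diff`,
#'   `ci_lower`, `ci_upper`.
#' @export
paired_t_test <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n) {
    stop("evaluation pairing error: x and y must have equal length", call. = FALSE)
  }
  if (n < 2L) {
    stop("evaluation error: paired t-test needs at least 2 pairs", call. = FALSE)
  }
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, df = n - 1L, p = 1, n = n, mean_diff = 0, sd_diff = 0,
                  ci_lower = 0, ci_upper = 0))
    }
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, n = n, mean_diff = m,
                sd_diff = 0, ci_lower = m, ci_upper = m))
  }
  ht <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       n = n, mean_diff = m, sd_diff = s,
       ci_lower = ht$conf.int[1L], ci_upper = ht$conf.int[2L])
}

#' Agreement statistics for one level
#'
#' Builds one evaluation row per approximation (ellipse, triangle,
#' rectangle, and SOA when present) at a given level: paired mean
#' difference +/- SD with 95% CI, percent error, Pearson correlation with
#' its qualitative band, and the paired t-test against the manual
#' measurement.
#'
#' @param cohort A `canal_cohort`.
#' @param approx Approximation table from [approximate_cohort()], optionally
#'   carrying an `soa_mm2` column (see [apply_soa()]).
#' @param level Level label to evaluate.
#' @param percent_error_mode Passed to [percent_error()].
#' @return Tibble with one row per approximation.
#' @export
evaluate_level <- function(cohort, approx = approximate_cohort(cohort), level,
                           percent_error_mode = "of_means") {
  lv <- as.character(canonical_level(level))
  if (is.na(lv)) stop("evaluation error: unknown level label: ", level, call. = FALSE)
  sel <- as.character(cohort$level) == lv
  if (!any(sel)) {
    stop("evaluation error: no records at level ", lv, call. = FALSE)
  }
  measured <- cohort$measured_area_mm2[sel]
  cols <- c(ellipse = "ellipse_mm2", triangle = "triangle_mm2",
            rectangle = "rectangle_mm2")
  if ("soa_mm2" %in% names(approx)) cols <- c(cols, soa = "soa_mm2")
  rows <- lapply(names(cols), function(nm) {
    a <- approx[[cols[[nm]]]][sel]
    md <- mean_difference(a, measured)
    tt <- paired_t_test(a, measured)
    r <- pearson_r(a, measured)
    tibble::tibble(
      level = lv, approximation = nm, n = sum(sel),
      mean_mm2 = mean(a), sd_mm2 = stats::sd(a),
      mean_diff_mm2 = md$mean, sd_diff_mm2 = md$sd,
      ci_lower_mm2 = tt$ci_lower, ci_upper_mm2 = tt$ci_upper,
      percent_error = percent_error(a, measured, mode = percent_error_mode),
      pearson_r = r, strength = correlation_strength(r),
      t_statistic = tt$t, p_value = tt$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$level <- factor(out$level, levels = cervical_levels())
  out
}

#' Agreement statistics for every populated level
#'
#' @inheritParams evaluate_level
#' @return Tibble of [evaluate_level()] rows stacked in anatomical order.
#' @export
evaluate_cohort <- function(cohort, approx = approximate_cohort(cohort),
                            percent_error_mode = "of_means") {
  levels_present <- intersect(cervical_levels(), unique(as.character(cohort$level)))
  if (length(levels_present) == 0L) {
    stop("evaluation error: cohort has no records", call. = FALSE)
  }
  dplyr::bind_rows(lapply(levels_present, function(lv) {
    evaluate_level(cohort, approx, lv, percent_error_mode = percent_error_mode)
  }))
}
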