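## Panel curation: quantitation-status rules and the low-exposure exclusion.

#' Assign a quantitation status to a measurement
#'
#' Applies the reporting rule for concentrations relative to the calibration
#' linearity range: values inside \code{[lo, hi]} are \code{quantified};
#' values below \code{lo} are retained as \code{estimated_below_lolr} when
#' the signal-to-noise ratio exceeds 10, otherwise the compound is
#' \code{not_detected}; absent values are \code{not_detected}. A value above
#' \code{hi} stays \code{quantified} but is flagged as extrapolated beyond
#' the calibration range.
#'
#' @param concentration ng/ml, a single non-negative value or \code{NA}
#'   (absent).
#' @param lolr Numeric length-2, \code{c(lo, hi)} linearity bounds, lo < hi.
#' @param sn_ratio Signal-to-noise ratio, or \code{NA} when no peak was
#'   found.
#' @return List with \code{status} (one of \code{quantified},
#'   \code{estimated_below_lolr}, \code{not_detected}), \code{concentration}
#'   (\code{NA} when not detected) and \code{above_range} flag.
#' @export
#' @examples
#' assignStatus(NA, c(0.05, 10))                 # not_detected
#' assignStatus(0.02, c(0.05, 10), sn_ratio = 15) # estimated_below_lolr
#' assignStatus(1.3, c(0.05, 10))                 # quantified
assignStatus <- function(concentration, lolr, sn_ratio = NA) {
  stopifnot(length(lolr) == 2, lolr[1] < lolr[2])
  if (!is.na(concentration) && concentration < 0)
    stop("concentration must be non-negative")
  if (is.na(concentration))
    return(list(status = "not_detected", concentration = NA_real_,
                above_range = FALSE))
  if (concentration < lolr[1]) {
    if (!is.na(sn_ratio) && sn_ratio > 10)
      return(list(status = "estimated_below_lolr",
                  concentration = concentration, above_range = FALSE))
    return(list(status = "not_detected", concentration = NA_real_,
                above_range = FALSE))
  }
  list(status = "quantified", concentration = concentration,
       above_range = concentration > lolr[2])
}

#' Exclude low-exposure patients
#'
#' Removes patients whose plasma tamoxifen concentration is below 10\% of
#' the mean tamoxifen level across the full input cohort. The mean is
#' computed once, over the pre-exclusion cohort, and the rule is applied in
#' a single pass (re-applying the operator to its own output can in
#' principle remove further patients because the mean shifts; this
#' implementation deliberately does not iterate). Ordering of retained
#' patients is preserved.
#'
#' @param x A [TamoxifenCohort-class]; every patient must have a quantified
#'   tamoxifen measurement.
#' @param fraction Exclusion fraction of the cohort mean (default 0.10).
#' @return List with \code{cohort} (retained patients),
#'   \code{excluded_ids}, \code{mean_tamoxifen} and \code{cutoff} (ng/ml).
#' @export
excludeLowExposure <- function(x, fraction = 0.10) {
  if (ncol(x) == 0) stop("empty cohort")
  tam <- concentrations(x)["tamoxifen", ]
  if (anyNA(tam))
    stop("tamoxifen not quantified for patient(s): ",
         paste(patientIds(x)[is.na(tam)], collapse = ", "))
  m <- mean(tam)
  cutoff <- fraction * m
  drop <- tam < cutoff
  list(cohort = x[, !drop], excluded_ids = patientIds(x)[drop],
       mean_tamoxifen = m, cutoff = cutoff)
}

#' Per-analyte cohort summary
#'
#' Summary statistics for each analyte in the layout of a steady-state
#' concentration table: mean, sample SD, median, min, max over patients in
#' whom the compound was detected, plus the not-detected count.
#' Estimated-below-LOLR values are included in the moments by default
#' (\code{include_estimated = FALSE} restricts to fully quantified values).
#'
#' @param x A [TamoxifenCohort-class].
#' @param include_estimated Include \code{estimated_below_lolr} values in
#'   the moments (default \code{TRUE}).
#' @return data.frame, one row per analyte: \code{analyte}, \code{label},
#'   \code{mean}, \code{sd}, \code{median}, \code{min}, \code{max},
#'   \code{n_not_detected}, \code{pct_not_detected}. Moments are \code{NA}
#'   for an analyte detected in no (or, for \code{sd}, one) patient.
#' @export
summarizeAnalytes <- function(x, include_estimated = TRUE) {
  conc <- concentrations(x)
  st <- measurementStatus(x)
  n <- ncol(x)
  rows <- lapply(ANALYTE_IDS, function(a) {
    v <- conc[a, ]
    keep <- st[a, ] != "not_detected"
    if (!include_estimated) keep <- keep & st[a, ] == "quantified"
    v <- v[keep]
    nd <- sum(st[a, ] == "not_detected")
    data.frame(
      analyte = a, label = unname(ANALYTE_LABELS[[a]]),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_,
      median = if (length(v)) median(v) else NA_real_,
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_,
      n_not_detected = nd,
      pct_not_detected = 100 * nd / n,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
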