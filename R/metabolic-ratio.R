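## The (Z)-endoxifen metabolic ratio (MR) and the efficacy-threshold
## machinery: MR = (Z)-endoxifen / sum of the 12 remaining measured
## compounds (tamoxifen itself included in the denominator; not-detected
## analytes contribute 0).

#' Threshold configuration
#'
#' Two distinct clinical reference levels are carried: the 5.97 ng/ml
#' (Z)-endoxifen efficacy threshold used for below-threshold prevalence, and
#' the rounded 6 ng/ml level at which the MR cutoff is read off the
#' regression line.
#'
#' @param endoxifen_threshold ng/ml; efficacy threshold (default 5.97).
#' @param cutoff_reference_level ng/ml; level at which the MR cutoff is
#'   derived (default 6.0).
#' @return A list of class \code{ThresholdConfig}.
#' @export
thresholdConfig <- function(endoxifen_threshold = 5.97,
                            cutoff_reference_level = 6.0) {
  stopifnot(endoxifen_threshold > 0, cutoff_reference_level > 0)
  structure(list(endoxifen_threshold = endoxifen_threshold,
                 cutoff_reference_level = cutoff_reference_level),
            class = "ThresholdConfig")
}

#' Compute the (Z)-endoxifen metabolic ratio
#'
#' For every patient, the ratio of the (Z)-endoxifen concentration to the
#' sum of the other 12 measured compounds (tamoxifen included). Not-detected
#' analytes enter the denominator as 0.
#'
#' @param x A [TamoxifenCohort-class].
#' @param numerator Analyte id of the numerator (default
#'   \code{"z_endoxifen"}; \code{"z_4oh_tam"} gives the secondary active
#'   metabolite's MR).
#' @return data.frame with \code{patient_id}, \code{mr}, \code{numerator},
#'   \code{denominator} (audit fields, ng/ml).
#' @export
#' @examples
#' sim <- simulateCohort(generatorConfig(n_patients = 20, seed = 1))
#' head(computeMR(sim$cohort))
computeMR <- function(x, numerator = "z_endoxifen") {
  stopifnot(numerator %in% ANALYTE_IDS)
  conc <- concentrations(x, zero_nd = TRUE)
  num <- conc[numerator, ]
  den <- colSums(conc) - num
  if (any(den <= 0))
    stop("degenerate panel: zero denominator for patient(s) ",
         paste(patientIds(x)[den <= 0], collapse = ", "))
  data.frame(patient_id = patientIds(x), mr = num / den,
             numerator = num, denominator = den,
             stringsAsFactors = FALSE)
}

#' Derive the MR cutoff from the concentration--MR regression
#'
#' Fits a simple linear regression between the (Z)-endoxifen concentration
#' and the MR across the cohort and reads the MR value corresponding to the
#' reference concentration off the fitted line. The default regresses MR on
#' concentration (with intercept) and evaluates the fit at
#' \code{cfg$cutoff_reference_level}; the reverse direction (concentration
#' on MR, solving for the MR at which the fitted concentration equals the
#' reference level) is also available since the choice is not determined by
#' the ratio's definition.
#'
#' @param mr Numeric vector of metabolic ratios.
#' @param concentration Numeric vector of (Z)-endoxifen levels (ng/ml).
#' @param cfg A [thresholdConfig()].
#' @param direction \code{"mr_on_concentration"} (default) or
#'   \code{"concentration_on_mr"}.
#' @return List with \code{cutoff}, \code{direction}, \code{intercept},
#'   \code{slope}, \code{n}.
#' @export
deriveMRCutoff <- function(mr, concentration, cfg = thresholdConfig(),
                           direction = c("mr_on_concentration",
                                         "concentration_on_mr")) {
  direction <- match.arg(direction)
  stopifnot(length(mr) == length(concentration))
  if (length(mr) < 3) stop("need at least 3 patients for the regression")
  if (length(unique(concentration)) < 2 || length(unique(mr)) < 2)
    stop("singular fit: constant input")
  if (direction == "mr_on_concentration") {
    fit <- lm(mr ~ concentration)
    b <- coef(fit)
    cutoff <- unname(b[1] + b[2] * cfg$cutoff_reference_level)
  } else {
    fit <- lm(concentration ~ mr)
    b <- coef(fit)
    if (abs(b[2]) < .Machine$double.eps) stop("singular fit: zero slope")
    cutoff <- unname((cfg$cutoff_reference_level - b[1]) / b[2])
  }
  list(cutoff = cutoff, direction = direction,
       intercept = unname(b[1]), slope = unname(b[2]), n = length(mr))
}

#' Concordance quadrants of concentration vs MR
#'
#' Classifies every patient by whether the (Z)-endoxifen concentration and
#' the MR fall below their respective thresholds, using strict \code{<}
#' comparisons for "below". The four quadrants partition the cohort:
#' concordant above, concordant below, low concentration despite a proper
#' metabolic profile (MR above cutoff), and the converse.
#'
#' @param concentration Numeric vector of (Z)-endoxifen levels (ng/ml).
#' @param mr Numeric vector of metabolic ratios, same length.
#' @param cutoff MR cutoff (e.g. from [deriveMRCutoff()]).
#' @param cfg A [thresholdConfig()]; its \code{cutoff_reference_level} is
#'   the concentration threshold used here, matching the level at which the
#'   cutoff was derived.
#' @return List with \code{counts} (named integer vector: \code{both_above},
#'   \code{both_below}, \code{low_conc_high_mr}, \code{high_conc_low_mr})
#'   and \code{quadrant} (per-patient factor).
#' @export
classifyQuadrants <- function(concentration, mr, cutoff,
                              cfg = thresholdConfig()) {
  stopifnot(length(concentration) == length(mr), cutoff > 0)
  low_c <- concentration < cfg$cutoff_reference_level
  low_m <- mr < cutoff
  q <- ifelse(!low_c & !low_m, "both_above",
       ifelse(low_c & low_m, "both_below",
       ifelse(low_c & !low_m, "low_conc_high_mr", "high_conc_low_mr")))
  q <- factor(q, levels = c("both_above", "both_below",
                            "low_conc_high_mr", "high_conc_low_mr"))
  list(counts = setNames(as.integer(table(q)), levels(q)), quadrant = q)
}

#' Below-threshold fraction by metabolizer category
#'
#' Fraction of patients in each metabolizer category whose (Z)-endoxifen
#' concentration lies strictly below the efficacy threshold.
#'
#' @param concentration Numeric vector of (Z)-endoxifen levels (ng/ml).
#' @param category Character or factor of metabolizer categories.
#' @param cfg A [thresholdConfig()]; uses \code{endoxifen_threshold}.
#' @return data.frame with \code{category}, \code{n}, \code{n_below},
#'   \code{fraction_below}; one row per category present plus an overall
#'   row.
#' @export
belowThresholdByCategory <- function(concentration, category,
                                     cfg = thresholdConfig()) {
  stopifnot(length(concentration) == length(category))
  cat_f <- factor(category, levels = CATEGORY_LEVELS)
  below <- concentration < cfg$endoxifen_threshold
  rows <- lapply(levels(cat_f), function(g) {
    sel <- !is.na(cat_f) & cat_f == g
    data.frame(category = g, n = sum(sel), n_below = sum(below[sel]),
               fraction_below = if (sum(sel)) mean(below[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    category = "overall", n = length(below), n_below = sum(below),
    fraction_below = mean(below), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
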