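#' @title TamoxifenCohort: analytes x patients container
#'
#' @description The central data container: a
#' \linkS4class{SummarizedExperiment} with the 13-analyte steady-state
#' concentration panel as rows and patients as columns. Two assays are
#' carried in parallel: \code{concentration} (ng/ml; \code{NA} where the
#' compound was not detected) and \code{status} (one of \code{quantified},
#' \code{estimated_below_lolr}, \code{not_detected}). Row metadata holds the
#' per-analyte linearity (LOLR) bounds; column metadata holds patient ids
#' and, once genotyping results are attached, the diplotype and metabolizer
#' category.
#'
#' @aliases TamoxifenCohort
#' @exportClass TamoxifenCohort
setClass("TamoxifenCohort", contains = "SummarizedExperiment")

setValidity("TamoxifenCohort", function(object) {
  msgs <- character()
  if (!all(c("concentration", "status") %in% assayNames(object)))
    msgs <- c(msgs, "assays 'concentration' and 'status' are required")
  if (!setequal(rownames(object), ANALYTE_IDS))
    msgs <- c(msgs, "rows must be exactly the 13 panel analytes")
  if ("status" %in% assayNames(object)) {
    st <- assay(object, "status")
    if (!all(st %in% MEASUREMENT_STATUSES))
      msgs <- c(msgs, "invalid measurement status value(s)")
    conc <- assay(object, "concentration")
    nd <- st == "not_detected"
    if (any(nd != is.na(conc)))
      msgs <- c(msgs,
                "status 'not_detected' must coincide exactly with absent concentrations")
    if (any(conc < 0, na.rm = TRUE))
      msgs <- c(msgs, "concentrations must be non-negative")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a TamoxifenCohort
#'
#' @param concentration Numeric matrix, 13 analytes (rows, named by
#'   [analyteIds()]) x patients; \code{NA} = not detected.
#' @param status Character matrix of matching shape; if \code{NULL}, derived
#'   from \code{concentration} and \code{lolr} via [assignStatus()] (with
#'   absent values treated as not detected).
#' @param patient_id Character vector of patient identifiers (columns).
#' @param lolr Optional data.frame with columns \code{analyte}, \code{lo},
#'   \code{hi}: per-analyte calibration linearity bounds in ng/ml.
#' @param colData Optional extra per-patient columns (e.g. diplotypes).
#' @return A [TamoxifenCohort-class] object.
#' @export
#' @examples
#' conc <- matrix(rlnorm(13 * 4, 1, 0.3), nrow = 13,
#'                dimnames = list(analyteIds(), paste0("P", 1:4)))
#' coh <- TamoxifenCohort(conc, patient_id = paste0("P", 1:4))
#' coh
TamoxifenCohort <- function(concentration, status = NULL,
                            patient_id = colnames(concentration),
                            lolr = NULL, colData = NULL) {
  if (is.null(patient_id))
    stop("'patient_id' is required (or name the matrix columns)")
  concentration <- as.matrix(concentration)
  concentration <- concentration[ANALYTE_IDS, , drop = FALSE]
  colnames(concentration) <- patient_id
  if (is.null(status)) {
    status <- concentration
    status[] <- "quantified"
    status[is.na(concentration)] <- "not_detected"
    if (!is.null(lolr)) {
      for (a in ANALYTE_IDS) {
        b <- lolr[lolr$analyte == a, , drop = FALSE]
        if (nrow(b) == 1) {
          v <- concentration[a, ]
          est <- !is.na(v) & v < b$lo
          status[a, est] <- "estimated_below_lolr"
        }
      }
    }
  } else {
    status <- as.matrix(status)[ANALYTE_IDS, , drop = FALSE]
    colnames(status) <- patient_id
  }
  rd <- DataFrame(analyte = ANALYTE_IDS,
                  label = unname(ANALYTE_LABELS[ANALYTE_IDS]),
                  row.names = ANALYTE_IDS)
  if (!is.null(lolr)) {
    rd$lolr_lo <- lolr$lo[match(ANALYTE_IDS, lolr$analyte)]
    rd$lolr_hi <- lolr$hi[match(ANALYTE_IDS, lolr$analyte)]
  }
  cd <- DataFrame(patient_id = patient_id, row.names = patient_id)
  if (!is.null(colData)) {
    extra <- DataFrame(colData)
    for (nm in setdiff(colnames(extra), "patient_id"))
      cd[[nm]] <- extra[[nm]]
  }
  se <- SummarizedExperiment(
    assays = list(concentration = concentration, status = status),
    rowData = rd, colData = cd)
  new("TamoxifenCohort", se)
}

setMethod("show", "TamoxifenCohort", function(object) {
  cat("TamoxifenCohort:", ncol(object), "patients x", nrow(object),
      "analytes\n")
  st <- assay(object, "status")
  cat("  not detected:", sum(st == "not_detected"),
      "| estimated below LOLR:", sum(st == "estimated_below_lolr"), "\n")
  if ("category" %in% colnames(colData(object))) {
    tab <- table(factor(colData(object)$category, levels = CATEGORY_LEVELS))
    cat("  categories:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else cat("  categories: not attached\n")
  invisible(object)
})

#' @describeIn TamoxifenCohort-class Concentration matrix (ng/ml; \code{NA}
#'   where not detected).
#' @param x,object A \code{TamoxifenCohort}.
#' @param zero_nd If \code{TRUE}, replace not-detected entries with 0 (the
#'   convention used in all downstream sums).
#' @export
concentrations <- function(x, zero_nd = FALSE) {
  m <- assay(x, "concentration")
  if (zero_nd) m[is.na(m)] <- 0
  m
}

#' @describeIn TamoxifenCohort-class Measurement status matrix.
#' @export
measurementStatus <- function(x) assay(x, "status")

#' @describeIn TamoxifenCohort-class Patient identifiers.
#' @export
patientIds <- function(x) colData(x)$patient_id

#' @describeIn TamoxifenCohort-class Metabolizer categories as an ordered
#'   factor (levels \code{categoryLevels()}), or \code{NULL} if genotypes
#'   have not been attached.
#' @export
phenotypeCategories <- function(x) {
  if (!"category" %in% colnames(colData(x))) return(NULL)
  factor(colData(x)$category, levels = CATEGORY_LEVELS, ordered = TRUE)
}

#' Attach diplotype calls to a cohort
#'
#' Joins a diplotype table (from [callCohortDiplotypes()]) to the cohort's
#' column metadata by patient id.
#'
#' @param x A [TamoxifenCohort-class].
#' @param diplotypes data.frame with \code{patient_id}, \code{genotype},
#'   \code{category} (and optionally \code{allele_a}, \code{allele_b},
#'   \code{duplicated}, \code{ambiguous}, \code{low_confidence}).
#' @return The cohort with genotype columns in \code{colData}.
#' @export
attachDiplotypes <- function(x, diplotypes) {
  idx <- match(patientIds(x), diplotypes$patient_id)
  if (anyNA(idx))
    stop("diplotype table lacks patient id(s): ",
         paste(patientIds(x)[is.na(idx)], collapse = ", "))
  for (nm in setdiff(names(diplotypes), "patient_id"))
    colData(x)[[nm]] <- diplotypes[[nm]][idx]
  x
}
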