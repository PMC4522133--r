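## TSV interfaces: genotype-assay tables, concentration panels and result
## serialisation. All files are plain tab-separated text with a header.

#' Read a genotype-assay table
#'
#' One row per patient: \code{patient_id}, one column per panel variant with
#' values \code{0/0}, \code{0/1}, \code{1/1} or \code{./.}, and an integer
#' \code{copy_number}.
#'
#' @param path TSV file path.
#' @param defs An [AlleleDefinitions-class]; the panel columns are checked.
#' @return data.frame.
#' @export
readGenotypeTable <- function(path, defs = loadAlleleDefinitions()) {
  gt <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", panelVariants(defs), "copy_number")
  miss <- setdiff(need, names(gt))
  if (length(miss))
    stop("genotype table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(gt$patient_id))
    stop("duplicate patient id(s) in genotype table")
  gt
}

#' Write a genotype-assay table
#' @param genotypes data.frame as produced by [simulateCohort()].
#' @param path Output TSV path.
#' @export
writeGenotypeTable <- function(genotypes, path) {
  write.table(genotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a concentration panel
#'
#' One row per patient: \code{patient_id}, one concentration column per
#' analyte id (empty/NA = not detected) and optional \code{<id>_status}
#' columns. Missing status columns are derived: absent values are not
#' detected; with \code{lolr} bounds, values below \code{lo} are estimated.
#'
#' @param path TSV file path.
#' @param lolr Optional data.frame (\code{analyte}, \code{lo}, \code{hi}).
#' @return A [TamoxifenCohort-class].
#' @export
readConcentrationTable <- function(path, lolr = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("missing 'patient_id' column")
  miss <- setdiff(ANALYTE_IDS, names(df))
  if (length(miss))
    stop("concentration table ", path, " lacks analyte column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id(s) in concentration table")
  conc <- t(as.matrix(df[, ANALYTE_IDS]))
  colnames(conc) <- df$patient_id
  st_cols <- paste0(ANALYTE_IDS, "_status")
  status <- NULL
  if (all(st_cols %in% names(df))) {
    status <- t(as.matrix(df[, st_cols]))
    rownames(status) <- ANALYTE_IDS
    colnames(status) <- df$patient_id
  }
  TamoxifenCohort(conc, status = status, patient_id = df$patient_id,
                  lolr = lolr)
}

#' Write a concentration panel
#' @param x A [TamoxifenCohort-class].
#' @param path Output TSV path.
#' @export
writeConcentrationTable <- function(x, path) {
  conc <- concentrations(x)
  st <- measurementStatus(x)
  df <- data.frame(patient_id = patientIds(x), stringsAsFactors = FALSE)
  for (a in ANALYTE_IDS) {
    df[[a]] <- conc[a, ]
    df[[paste0(a, "_status")]] <- st[a, ]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Default linearity bounds
#'
#' The per-analyte calibration linearity ranges shipped with the analyte
#' model configuration.
#'
#' @param analyte_model Path to the analyte model YAML.
#' @return data.frame with \code{analyte}, \code{lo}, \code{hi} (ng/ml).
#' @export
defaultLolrBounds <- function(analyte_model = system.file(
                                "extdata", "analyte_model.yaml",
                                package = "TamoxPGx")) {
  raw <- yaml::read_yaml(analyte_model)$analytes
  data.frame(analyte = vapply(raw, `[[`, "", "id"),
             lo = vapply(raw, `[[`, 0, "lolr_lo"),
             hi = vapply(raw, `[[`, 0, "lolr_hi"),
             stringsAsFactors = FALSE)
}
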