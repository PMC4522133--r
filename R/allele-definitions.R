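#' @title CYP2D6 star-allele definition table
#'
#' @description An \code{AlleleDefinitions} object holds the variant panel and
#' the star-allele definition table used by the diplotype caller: one row per
#' allele with its defining variant set, activity class (EM, IM or PM) and a
#' match priority (defaults to the number of defining variants, so more
#' specific alleles win ties). \code{"*1"} is the mandatory default allele
#' with an empty defining set; the gene deletion allele (\code{"*5"}) carries
#' no variants and is recognised through copy number instead.
#'
#' @slot alleles data.frame with columns \code{star}, \code{activity},
#'   \code{deletion}, \code{priority} and list-column \code{variants}.
#' @slot panel character vector of panel variant identifiers.
#'
#' @aliases AlleleDefinitions
#' @exportClass AlleleDefinitions
setClass("AlleleDefinitions",
         slots = c(alleles = "data.frame", panel = "character"))

setValidity("AlleleDefinitions", function(object) {
  al <- object@alleles
  msgs <- character()
  need <- c("star", "activity", "deletion", "priority", "variants")
  if (!all(need %in% names(al)))
    return(paste("allele table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(al$star))
    msgs <- c(msgs, paste("duplicate star allele name(s):",
                          paste(unique(al$star[duplicated(al$star)]), collapse = ", ")))
  if (!"*1" %in% al$star)
    msgs <- c(msgs, "the default allele \"*1\" is mandatory")
  if (!all(al$activity %in% c("EM", "IM", "PM")))
    msgs <- c(msgs, "activity class must be one of EM, IM, PM")
  bad <- setdiff(unlist(al$variants), object@panel)
  if (length(bad))
    msgs <- c(msgs, paste("allele references unknown variant id(s):",
                          paste(bad, collapse = ", ")))
  for (i in seq_len(nrow(al)))
    if (anyDuplicated(al$variants[[i]]))
      msgs <- c(msgs, paste("duplicate variant ids within allele", al$star[i]))
  if ("*1" %in% al$star && length(al$variants[[match("*1", al$star)]]) > 0)
    msgs <- c(msgs, "\"*1\" must have an empty defining variant set")
  if (sum(al$deletion) > 1)
    msgs <- c(msgs, "at most one deletion allele is supported")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "AlleleDefinitions", function(object) {
  al <- object@alleles
  cat("AlleleDefinitions:", nrow(al), "alleles over",
      length(object@panel), "panel variants\n")
  for (i in seq_len(nrow(al))) {
    v <- al$variants[[i]]
    cat(sprintf("  %-4s %s %s%s\n", al$star[i], al$activity[i],
                if (al$deletion[i]) "[gene deletion]"
                else if (length(v)) paste(v, collapse = ", ") else "[reference]",
                ""))
  }
  invisible(object)
})

#' Load a star-allele definition table
#'
#' Reads a YAML definition file (see the shipped
#' \code{extdata/cyp2d6_alleles.yaml} for the schema) and validates it:
#' star names must be unique, \code{"*1"} must be present with an empty
#' defining set, and every defining variant must belong to the declared
#' panel.
#'
#' @param path Path to a YAML file. Defaults to the shipped 11-allele table
#'   (\code{*1}--\code{*7}, \code{*9}, \code{*10}, \code{*17}, \code{*41}).
#' @return A validated [AlleleDefinitions-class] object.
#' @export
#' @examples
#' defs <- loadAlleleDefinitions()
#' defs
loadAlleleDefinitions <- function(path = system.file("extdata",
                                                     "cyp2d6_alleles.yaml",
                                                     package = "TamoxPGx")) {
  if (!file.exists(path)) stop("allele definition file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$alleles) || is.null(raw$panel_variants))
    stop("definition file must contain 'panel_variants' and 'alleles'")
  star <- vapply(raw$alleles, function(a) as.character(a$star), "")
  activity <- vapply(raw$alleles, function(a) as.character(a$activity), "")
  deletion <- vapply(raw$alleles, function(a) isTRUE(a$deletion), NA)
  variants <- lapply(raw$alleles, function(a) as.character(unlist(a$variants)))
  priority <- vapply(seq_along(raw$alleles), function(i) {
    p <- raw$alleles[[i]]$priority
    if (is.null(p)) length(variants[[i]]) else as.integer(p)
  }, 0L)
  al <- data.frame(star = star, activity = activity, deletion = deletion,
                   priority = priority, stringsAsFactors = FALSE)
  al$variants <- variants
  obj <- new("AlleleDefinitions", alleles = al,
             panel = as.character(unlist(raw$panel_variants)))
  validObject(obj)
  obj
}

#' Variant panel of a definition table
#' @param defs An [AlleleDefinitions-class] object.
#' @return Character vector of panel variant ids.
#' @export
panelVariants <- function(defs) defs@panel

#' Allele activity classes
#' @param defs An [AlleleDefinitions-class] object.
#' @return Named character vector star -> activity class.
#' @export
alleleActivity <- function(defs) {
  setNames(defs@alleles$activity, defs@alleles$star)
}

## star allele canonical ordering: numeric part of the name
starRank <- function(star) {
  as.numeric(sub("^\\*", "", star))
}

## deletion allele name, or NA if the table has none
deletionAllele <- function(defs) {
  del <- defs@alleles$star[defs@alleles$deletion]
  if (length(del)) del else NA_character_
}
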