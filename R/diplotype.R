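## Diplotype calling: translate an 11-variant call vector plus a gene copy
## number into a CYP2D6 star-allele pair.
##
## Matching model: an unphased diplotype (a, b) implies, at every panel
## variant, an alternate-allele dose equal to the number of the two alleles
## whose defining set contains that variant.  A candidate pair is consistent
## when the implied dose equals the observed dose (hom_ref = 0, het = 1,
## hom_alt = 2) at every *called* variant.  With one gene copy the single
## retained allele presents its defining variants as apparently homozygous.

VARIANT_STATES <- c("hom_ref", "het", "hom_alt", "no_call")

stateToDose <- function(state) {
  unname(c(hom_ref = 0, het = 1, hom_alt = 2, no_call = NA_real_)[state])
}

## genotype-string (0/0, 0/1, 1/1, ./.) <-> state helpers for the TSV layer
gtToState <- function(gt) {
  map <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
           "1/1" = "hom_alt", "./." = "no_call")
  out <- map[gt]
  if (anyNA(out))
    stop("malformed genotype string(s): ",
         paste(unique(gt[is.na(out)]), collapse = ", "))
  unname(out)
}

stateToGt <- function(state) {
  unname(c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
           no_call = "./.")[state])
}

#' Call a CYP2D6 star-allele diplotype
#'
#' Translates one patient's variant-panel calls and gene copy number into a
#' star-allele pair. Copy number 1 forces one allele to the deletion allele
#' (\code{*5}) and treats the remaining haplotype as hemizygous (its defining
#' variants present as homozygous); copy number 0 yields \code{*5/*5}; copy
#' number 3 or more marks the diplotype as duplicated. Variants with a
#' \code{no_call} state exclude the alleles they define from matching and
#' flag the result low-confidence. Among consistent pairs the most
#' parsimonious assignment wins (fewest non-reference alleles, then highest
#' total match priority); equally ranked alternatives are reported in
#' \code{ambiguous_alternatives}, never silently dropped.
#'
#' @param calls Named character vector of states (\code{hom_ref}, \code{het},
#'   \code{hom_alt}, \code{no_call}); names are panel variant ids. All panel
#'   variants must be present.
#' @param copies Non-negative integer gene copy number (2 is normal).
#' @param defs An [AlleleDefinitions-class] object.
#' @param pass_qc Logical; copy-number assay QC flag. \code{FALSE} is an
#'   error.
#' @return List with elements \code{allele_a}, \code{allele_b} (canonically
#'   sorted), \code{duplicated}, \code{ambiguous_alternatives} (list of
#'   character pairs), \code{low_confidence} and \code{excluded_alleles}.
#' @export
#' @examples
#' defs <- loadAlleleDefinitions()
#' calls <- setNames(rep("hom_ref", length(panelVariants(defs))),
#'                   panelVariants(defs))
#' callDiplotype(calls, copies = 2, defs)           # *1/*1
#' calls["1846G>A"] <- "het"
#' callDiplotype(calls, copies = 2, defs)           # *1/*4
callDiplotype <- function(calls, copies, defs, pass_qc = TRUE) {
  if (!isTRUE(pass_qc))
    stop("copy-number assay failed QC; diplotype not callable")
  if (length(copies) != 1L || is.na(copies) || copies < 0)
    stop("'copies' must be a single non-negative integer")
  panel <- panelVariants(defs)
  if (!all(panel %in% names(calls)))
    stop("missing panel variant(s): ",
         paste(setdiff(panel, names(calls)), collapse = ", "))
  calls <- calls[panel]
  if (!all(calls %in% VARIANT_STATES))
    stop("invalid variant state(s): ",
         paste(unique(calls[!calls %in% VARIANT_STATES]), collapse = ", "))

  al <- defs@alleles
  del <- deletionAllele(defs)
  no_call <- names(calls)[calls == "no_call"]
  excluded <- al$star[vapply(al$variants,
                             function(v) any(v %in% no_call), NA)]
  usable <- al[!al$star %in% excluded & !al$deletion, , drop = FALSE]
  obs <- stateToDose(calls)            # NA at no_call positions
  called <- !is.na(obs)

  ## incidence matrix: usable alleles x panel variants
  inc <- vapply(usable$variants,
                function(v) as.numeric(panel %in% v),
                numeric(length(panel)))
  inc <- matrix(inc, nrow = length(panel))  # variants x alleles

  if (copies == 0) {
    if (is.na(del)) stop("copy number 0 but no deletion allele defined")
    return(newDiplotype(del, del, FALSE, list(), length(no_call) > 0,
                        excluded))
  }

  consistent <- list()
  score <- list()   # c(n_nonref, total_priority)
  if (copies == 1) {
    if (is.na(del)) stop("copy number 1 but no deletion allele defined")
    ## hemizygous: single allele x, variants in x present as hom_alt (dose 2)
    for (i in seq_len(nrow(usable))) {
      implied <- 2 * inc[, i]
      if (all(implied[called] == obs[called])) {
        consistent[[length(consistent) + 1L]] <- c(usable$star[i], del)
        score[[length(score) + 1L]] <-
          c(as.numeric(usable$star[i] != "*1"), usable$priority[i])
      }
    }
  } else {
    for (i in seq_len(nrow(usable))) {
      for (j in i:nrow(usable)) {
        implied <- inc[, i] + inc[, j]
        if (all(implied[called] == obs[called])) {
          pair <- c(usable$star[i], usable$star[j])
          consistent[[length(consistent) + 1L]] <- pair
          score[[length(score) + 1L]] <-
            c(sum(pair != "*1"), usable$priority[i] + usable$priority[j])
        }
      }
    }
  }

  if (!length(consistent)) {
    alt_vars <- names(calls)[called & obs > 0]
    stop("variant states inconsistent with every allele pair",
         if (length(alt_vars)) paste0(" (conflicting variants: ",
                                      paste(alt_vars, collapse = ", "), ")"))
  }

  sc <- do.call(rbind, score)
  ord <- order(sc[, 1], -sc[, 2])
  best <- ord[1]
  ties <- ord[sc[ord, 1] == sc[best, 1] & sc[ord, 2] == sc[best, 2]]
  ties <- setdiff(ties, best)
  pair <- sortAlleles(consistent[[best]])
  alts <- lapply(ties, function(k) sortAlleles(consistent[[k]]))
  newDiplotype(pair[1], pair[2], copies >= 3, alts,
               length(no_call) > 0, excluded)
}

sortAlleles <- function(pair) pair[order(starRank(pair))]

newDiplotype <- function(a, b, duplicated, alts, low_conf, excluded) {
  list(allele_a = a, allele_b = b, duplicated = duplicated,
       ambiguous_alternatives = alts,
       low_confidence = low_conf,
       excluded_alleles = as.character(excluded))
}

#' Format a diplotype as a genotype label
#'
#' @param allele_a,allele_b Star allele names.
#' @param duplicated Logical duplication flag; appends \code{" (xN)"}.
#' @return Character label such as \code{"*1/*4"} or \code{"*1/*2 (xN)"}.
#' @export
diplotypeLabel <- function(allele_a, allele_b, duplicated = FALSE) {
  paste0(allele_a, "/", allele_b, ifelse(duplicated, " (xN)", ""))
}

#' Classify a diplotype into a metabolizer category
#'
#' Maps the two allele activity classes onto the seven ordered functional
#' categories. A gene duplication promotes a fully functional (EM/EM) pair
#' to EM/UM; a duplication on a pair carrying a reduced or null allele has no
#' category in the scheme and is an explicit indeterminate case.
#'
#' @param allele_a,allele_b Star allele names present in \code{defs}.
#' @param duplicated Logical duplication flag.
#' @param defs An [AlleleDefinitions-class] object.
#' @param indeterminate Either \code{"error"} (default) or \code{"flag"}:
#'   how to treat a duplication combined with a non-EM allele. With
#'   \code{"flag"} the category of the unduplicated pair is returned with
#'   attribute \code{indeterminate_um = TRUE}.
#' @return Category label, one of \code{categoryLevels()}.
#' @export
#' @examples
#' defs <- loadAlleleDefinitions()
#' classifyPhenotype("*4", "*4", FALSE, defs)          # "PM/PM"
#' classifyPhenotype("*1", "*41", FALSE, defs)         # "EM/IM"
#' classifyPhenotype("*1", "*2", TRUE, defs)           # "EM/UM"
classifyPhenotype <- function(allele_a, allele_b, duplicated = FALSE,
                              defs = loadAlleleDefinitions(),
                              indeterminate = c("error", "flag")) {
  indeterminate <- match.arg(indeterminate)
  act <- alleleActivity(defs)
  if (!allele_a %in% names(act) || !allele_b %in% names(act))
    stop("unknown allele(s): ",
         paste(setdiff(c(allele_a, allele_b), names(act)), collapse = ", "))
  cls <- c(act[[allele_a]], act[[allele_b]])
  ord <- c(EM = 1, IM = 2, PM = 3)
  cls <- cls[order(ord[cls])]
  label <- paste(cls[1], cls[2], sep = "/")
  if (isTRUE(duplicated)) {
    if (identical(label, "EM/EM")) return("EM/UM")
    if (indeterminate == "error")
      stop("duplication combined with a non-EM allele (", allele_a, "/",
           allele_b, "): metabolizer category is indeterminate")
    attr(label, "indeterminate_um") <- TRUE
  }
  label
}

#' Call diplotypes and categories for a genotype table
#'
#' Vectorised convenience wrapper: applies [callDiplotype()] and
#' [classifyPhenotype()] to every row of a genotype call table (the format
#' read by [readGenotypeTable()]).
#'
#' @param genotypes data.frame with \code{patient_id}, one \code{0/0}-style
#'   column per panel variant, and \code{copy_number}.
#' @param defs An [AlleleDefinitions-class] object.
#' @return A data.frame with one row per patient: \code{patient_id},
#'   \code{allele_a}, \code{allele_b}, \code{duplicated}, \code{genotype}
#'   (display label), \code{category}, \code{ambiguous},
#'   \code{low_confidence}.
#' @export
callCohortDiplotypes <- function(genotypes, defs = loadAlleleDefinitions()) {
  panel <- panelVariants(defs)
  if (!all(panel %in% names(genotypes)))
    stop("genotype table lacks panel variant column(s): ",
         paste(setdiff(panel, names(genotypes)), collapse = ", "))
  if (!"copy_number" %in% names(genotypes))
    stop("genotype table lacks 'copy_number'")
  out <- vector("list", nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    calls <- setNames(gtToState(unlist(genotypes[i, panel])), panel)
    d <- callDiplotype(calls, genotypes$copy_number[i], defs)
    out[[i]] <- data.frame(
      patient_id = genotypes$patient_id[i],
      allele_a = d$allele_a, allele_b = d$allele_b,
      duplicated = d$duplicated,
      genotype = diplotypeLabel(d$allele_a, d$allele_b, d$duplicated),
      category = classifyPhenotype(d$allele_a, d$allele_b, d$duplicated,
                                   defs),
      ambiguous = length(d$ambiguous_alternatives) > 0,
      low_confidence = d$low_confidence,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Genotype and category frequency table
#'
#' Tabulates diplotype and metabolizer-category counts and percentages for a
#' cohort, in the layout of a genotype-frequency report: per-diplotype rows
#' nested within category blocks, plus a per-category summary.
#'
#' @param genotype Character vector of genotype display labels (e.g.
#'   \code{"*1/*4"}, \code{"*1/*2 (xN)"}).
#' @param category Character vector of metabolizer categories, same length.
#' @return List with data.frames \code{by_genotype} (category, genotype, n,
#'   pct) and \code{by_category} (category, n, pct); percentages are of the
#'   cohort size.
#' @export
genotypeFrequencyTable <- function(genotype, category) {
  stopifnot(length(genotype) == length(category), length(genotype) >= 1)
  n <- length(genotype)
  cat_f <- factor(category, levels = CATEGORY_LEVELS)
  if (anyNA(cat_f)) stop("unknown category label(s)")
  by_g <- as.data.frame(table(category = cat_f, genotype = genotype),
                        stringsAsFactors = FALSE)
  by_g <- by_g[by_g$Freq > 0, , drop = FALSE]
  by_g <- by_g[order(factor(by_g$category, levels = CATEGORY_LEVELS),
                     -by_g$Freq), , drop = FALSE]
  names(by_g)[3] <- "n"
  by_g$pct <- 100 * by_g$n / n
  by_c <- as.data.frame(table(category = cat_f), stringsAsFactors = FALSE)
  names(by_c)[2] <- "n"
  by_c$pct <- 100 * by_c$n / n
  rownames(by_g) <- rownames(by_c) <- NULL
  list(by_genotype = by_g, by_category = by_c)
}

#' Reconstruct the assay calls implied by a diplotype
#'
#' The inverse of [callDiplotype()] for round-trip testing and simulation:
#' emits the unique variant-state vector and copy number implied by a
#' star-allele pair.
#'
#' @param allele_a,allele_b Star allele names present in \code{defs}.
#' @param duplicated Logical; if \code{TRUE} the copy number is 3.
#' @param defs An [AlleleDefinitions-class] object.
#' @return List with \code{calls} (named state vector over the panel) and
#'   \code{copies}.
#' @export
#' @examples
#' defs <- loadAlleleDefinitions()
#' simulateAssayCalls("*4", "*5", defs = defs)  # hom_alt at 1846G>A, copies 1
simulateAssayCalls <- function(allele_a, allele_b, duplicated = FALSE,
                               defs = loadAlleleDefinitions()) {
  al <- defs@alleles
  panel <- panelVariants(defs)
  for (a in c(allele_a, allele_b))
    if (!a %in% al$star) stop("unknown allele: ", a)
  del <- deletionAllele(defs)
  pair <- c(allele_a, allele_b)
  is_del <- !is.na(del) & pair == del
  copies <- 2L - sum(is_del)
  if (isTRUE(duplicated)) {
    if (copies < 2L)
      stop("a deletion allele cannot carry a duplication")
    copies <- 3L
  }
  kept <- pair[!is_del]
  dose <- setNames(numeric(length(panel)), panel)
  for (a in kept) {
    v <- al$variants[[match(a, al$star)]]
    if (!length(v) && a != "*1")
      stop("allele ", a, " has no defining variants; its assay signature ",
           "is not representable")
    dose[v] <- dose[v] + 1
  }
  ## hemizygous alt variants present as homozygous in the assay
  if (copies == 1L) dose[dose > 0] <- 2
  states <- c("hom_ref", "het", "hom_alt")[dose + 1]
  list(calls = setNames(states, panel), copies = copies)
}
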