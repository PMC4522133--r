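## Shared fixtures: the shipped allele definitions, the published
## genotype-frequency table expanded to per-patient diplotypes, and small
## cohort builders.

DEFS <- loadAlleleDefinitions()

## The 279-patient genotype-frequency table (diplotype, count, duplication),
## expanded to one row per patient.
publishedDiplotypes <- function() {
  rows <- list(
    c("*1", "*2", 44, FALSE), c("*1", "*1", 33, FALSE),
    c("*2", "*2", 10, FALSE),
    c("*1", "*41", 24, FALSE), c("*2", "*41", 10, FALSE),
    c("*1", "*10", 7, FALSE), c("*2", "*10", 2, FALSE),
    c("*1", "*4", 51, FALSE), c("*2", "*4", 30, FALSE),
    c("*1", "*5", 6, FALSE), c("*1", "*3", 4, FALSE),
    c("*2", "*5", 3, FALSE), c("*1", "*6", 1, FALSE),
    c("*2", "*3", 1, FALSE), c("*2", "*6", 1, FALSE),
    c("*41", "*41", 1, FALSE), c("*10", "*10", 1, FALSE),
    c("*10", "*41", 1, FALSE),
    c("*4", "*41", 6, FALSE), c("*4", "*10", 3, FALSE),
    c("*4", "*17", 1, FALSE), c("*5", "*41", 1, FALSE),
    c("*4", "*4", 15, FALSE), c("*3", "*4", 2, FALSE),
    c("*4", "*5", 2, FALSE), c("*4", "*6", 1, FALSE),
    c("*1", "*2", 10, TRUE), c("*1", "*1", 5, TRUE),
    c("*2", "*2", 3, TRUE))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(allele_a = r[1], allele_b = r[2],
               duplicated = as.logical(r[4]),
               stringsAsFactors = FALSE)[rep(1, as.integer(r[3])), ]
  }))
  rownames(out) <- NULL
  out
}

## an all-reference call vector over the shipped panel
refCalls <- function(defs = DEFS) {
  setNames(rep("hom_ref", length(panelVariants(defs))),
           panelVariants(defs))
}

## minimal cohort with a given tamoxifen vector; remaining analytes held at
## small constant levels so panel sums stay positive
toyCohort <- function(tamoxifen, z_endoxifen = rep(5, length(tamoxifen)),
                      other = 1) {
  n <- length(tamoxifen)
  ids <- sprintf("T%02d", seq_len(n))
  conc <- matrix(other, nrow = 13, ncol = n,
                 dimnames = list(analyteIds(), ids))
  conc["tamoxifen", ] <- tamoxifen
  conc["z_endoxifen", ] <- z_endoxifen
  TamoxifenCohort(conc, patient_id = ids)
}

## independent exhaustive-enumeration oracle for diplotype calling:
## checks that a called pair is consistent with the observed doses and that
## no consistent pair is strictly more parsimonious / higher priority
oracleConsistentPairs <- function(calls, copies, defs = DEFS) {
  al <- defs@alleles
  panel <- panelVariants(defs)
  dose_obs <- sapply(calls[panel], function(s)
    switch(s, hom_ref = 0, het = 1, hom_alt = 2, no_call = NA))
  no_call_vars <- panel[is.na(dose_obs)]
  usable <- al[!al$deletion &
                 !sapply(al$variants, function(v) any(v %in% no_call_vars)), ]
  pairs <- list()
  if (copies >= 2) {
    for (i in seq_len(nrow(usable))) for (j in i:nrow(usable)) {
      d <- sapply(panel, function(v)
        (v %in% usable$variants[[i]]) + (v %in% usable$variants[[j]]))
      if (all(d[!is.na(dose_obs)] == dose_obs[!is.na(dose_obs)]))
        pairs[[length(pairs) + 1]] <- list(
          pair = sort(c(usable$star[i], usable$star[j])),
          nonref = sum(c(usable$star[i], usable$star[j]) != "*1"),
          prio = usable$priority[i] + usable$priority[j])
    }
  } else if (copies == 1) {
    for (i in seq_len(nrow(usable))) {
      d <- sapply(panel, function(v) 2 * (v %in% usable$variants[[i]]))
      if (all(d[!is.na(dose_obs)] == dose_obs[!is.na(dose_obs)]))
        pairs[[length(pairs) + 1]] <- list(
          pair = sort(c(usable$star[i], "*5")),
          nonref = as.numeric(usable$star[i] != "*1"),
          prio = usable$priority[i])
    }
  }
  pairs
}
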