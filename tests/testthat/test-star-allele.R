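test_that("shipped definition table loads with the 11 expected alleles", {
  expect_s4_class(DEFS, "AlleleDefinitions")
  expect_setequal(DEFS@alleles$star,
                  c("*1", "*2", "*3", "*4", "*5", "*6", "*7", "*9", "*10",
                    "*17", "*41"))
  expect_length(panelVariants(DEFS), 11)
  expect_length(DEFS@alleles$variants[[match("*1", DEFS@alleles$star)]], 0)
  act <- alleleActivity(DEFS)
  expect_equal(unname(act[c("*3", "*4", "*5", "*6", "*7")]),
               rep("PM", 5))
  expect_equal(unname(act[c("*9", "*10", "*17", "*41")]), rep("IM", 4))
})

test_that("malformed definition tables are rejected", {
  write_defs <- function(body) {
    f <- tempfile(fileext = ".yaml")
    writeLines(body, f)
    f
  }
  no_star1 <- write_defs(c(
    "panel_variants: ['v1']",
    "alleles:",
    "  - {star: '*4', activity: PM, variants: ['v1']}"))
  expect_error(loadAlleleDefinitions(no_star1), "\\*1")
  dup_name <- write_defs(c(
    "panel_variants: ['v1', 'v2']",
    "alleles:",
    "  - {star: '*1', activity: EM, variants: []}",
    "  - {star: '*4', activity: PM, variants: ['v1']}",
    "  - {star: '*4', activity: PM, variants: ['v2']}"))
  expect_error(loadAlleleDefinitions(dup_name), "duplicate star")
  unknown_var <- write_defs(c(
    "panel_variants: ['v1']",
    "alleles:",
    "  - {star: '*1', activity: EM, variants: []}",
    "  - {star: '*4', activity: PM, variants: ['v9']}"))
  expect_error(loadAlleleDefinitions(unknown_var), "unknown variant")
})

test_that("diplotype calling resolves reference, het, hemizygous and deleted genotypes", {
  calls <- refCalls()
  d <- callDiplotype(calls, 2, DEFS)
  expect_equal(c(d$allele_a, d$allele_b), c("*1", "*1"))
  expect_false(d$duplicated)
  expect_length(d$ambiguous_alternatives, 0)

  calls["1846G>A"] <- "het"
  d <- callDiplotype(calls, 2, DEFS)
  expect_equal(c(d$allele_a, d$allele_b), c("*1", "*4"))

  calls["1846G>A"] <- "hom_alt"
  d <- callDiplotype(calls, 1, DEFS)
  expect_equal(c(d$allele_a, d$allele_b), c("*4", "*5"))

  d <- callDiplotype(refCalls(), 0, DEFS)
  expect_equal(c(d$allele_a, d$allele_b), c("*5", "*5"))

  calls <- refCalls()
  calls[c("-1584C>G", "2851C>T", "4181G>C")] <- "het"
  d <- callDiplotype(calls, 3, DEFS)
  expect_equal(diplotypeLabel(d$allele_a, d$allele_b, d$duplicated),
               "*1/*2 (xN)")
})

test_that("inconsistent call vectors raise errors naming the conflict", {
  calls <- refCalls()
  calls["4181G>C"] <- "het"   # *2 signature fragment: no pair explains it
  expect_error(callDiplotype(calls, 2, DEFS), "inconsistent")
  calls <- refCalls()
  calls["1846G>A"] <- "hom_alt"
  calls["2549delA"] <- "hom_alt"  # *4/*4 and *3/*3 mutually exclusive
  expect_error(callDiplotype(calls, 2, DEFS), "1846G>A")
  expect_error(callDiplotype(refCalls(), 2, DEFS, pass_qc = FALSE), "QC")
})

test_that("no_call excludes affected alleles and flags low confidence", {
  calls <- refCalls()
  calls["1846G>A"] <- "no_call"
  d <- callDiplotype(calls, 2, DEFS)
  expect_equal(c(d$allele_a, d$allele_b), c("*1", "*1"))
  expect_true(d$low_confidence)
  expect_true("*4" %in% d$excluded_alleles)
})

test_that("equally parsimonious assignments are reported, not dropped", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "panel_variants: ['v1']",
    "alleles:",
    "  - {star: '*1', activity: EM, variants: []}",
    "  - {star: '*70', activity: IM, variants: ['v1']}",
    "  - {star: '*71', activity: PM, variants: ['v1']}"), f)
  toy <- loadAlleleDefinitions(f)
  d <- callDiplotype(c("v1" = "het"), 2, toy)
  expect_length(d$ambiguous_alternatives, 1)
  got <- sort(c(paste(d$allele_a, d$allele_b),
                paste(d$ambiguous_alternatives[[1]], collapse = " ")))
  expect_equal(got, c("*1 *70", "*1 *71"))
})

test_that("calls agree with the exhaustive-enumeration oracle", {
  set.seed(31)
  gts <- sampleGenotypes(generatorConfig(n_patients = 80), DEFS, seed = 31)
  for (i in seq_len(nrow(gts))) {
    ac <- simulateAssayCalls(gts$allele_a[i], gts$allele_b[i],
                             gts$duplicated[i], DEFS)
    d <- callDiplotype(ac$calls, ac$copies, DEFS)
    cons <- oracleConsistentPairs(ac$calls, ac$copies, DEFS)
    expect_gt(length(cons), 0)
    called <- sort(c(d$allele_a, d$allele_b))
    keys <- vapply(cons, function(p) paste(p$pair, collapse = "/"), "")
    expect_true(paste(called, collapse = "/") %in% keys)
    this <- cons[[match(paste(called, collapse = "/"), keys)]]
    better <- vapply(cons, function(p)
      p$nonref < this$nonref ||
        (p$nonref == this$nonref && p$prio > this$prio), NA)
    expect_false(any(better))
  }
})

test_that("round-trip: simulated assay calls recover every diplotype exactly", {
  gts <- sampleGenotypes(generatorConfig(n_patients = 150), DEFS, seed = 7)
  ambiguous <- 0
  for (i in seq_len(nrow(gts))) {
    ac <- simulateAssayCalls(gts$allele_a[i], gts$allele_b[i],
                             gts$duplicated[i], DEFS)
    d <- callDiplotype(ac$calls, ac$copies, DEFS)
    expect_equal(c(d$allele_a, d$allele_b),
                 c(gts$allele_a[i], gts$allele_b[i]))
    expect_equal(d$duplicated, gts$duplicated[i])
    ambiguous <- ambiguous + length(d$ambiguous_alternatives)
  }
  expect_equal(ambiguous, 0)
})

test_that("phenotype classification is symmetric and handles duplication", {
  expect_equal(classifyPhenotype("*4", "*4", FALSE, DEFS), "PM/PM")
  expect_equal(classifyPhenotype("*1", "*41", FALSE, DEFS), "EM/IM")
  expect_equal(classifyPhenotype("*41", "*1", FALSE, DEFS), "EM/IM")
  expect_equal(classifyPhenotype("*1", "*2", TRUE, DEFS), "EM/UM")
  expect_equal(classifyPhenotype("*10", "*4", FALSE, DEFS), "IM/PM")
  pairs <- expand.grid(a = DEFS@alleles$star, b = DEFS@alleles$star,
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs)))
    expect_equal(classifyPhenotype(pairs$a[k], pairs$b[k], FALSE, DEFS),
                 classifyPhenotype(pairs$b[k], pairs$a[k], FALSE, DEFS))
  expect_error(classifyPhenotype("*1", "*4", TRUE, DEFS), "indeterminate")
  flagged <- classifyPhenotype("*1", "*4", TRUE, DEFS,
                               indeterminate = "flag")
  expect_equal(as.character(flagged), "EM/PM")
  expect_true(attr(flagged, "indeterminate_um"))
})

test_that("frequency tables partition the cohort", {
  dip <- publishedDiplotypes()
  cats <- vapply(seq_len(nrow(dip)), function(i)
    classifyPhenotype(dip$allele_a[i], dip$allele_b[i],
                      dip$duplicated[i], DEFS), "")
  labels <- diplotypeLabel(dip$allele_a, dip$allele_b, dip$duplicated)
  ft <- genotypeFrequencyTable(labels, cats)
  expect_equal(sum(ft$by_category$n), nrow(dip))
  expect_equal(sum(ft$by_genotype$n), nrow(dip))
  expect_equal(sum(ft$by_category$pct), 100, tolerance = 1e-9)
  for (g in ft$by_category$category)
    expect_equal(ft$by_category$n[ft$by_category$category == g],
                 sum(ft$by_genotype$n[ft$by_genotype$category == g]))
  single <- genotypeFrequencyTable("*1/*1", "EM/EM")
  expect_equal(single$by_category$pct[single$by_category$category == "EM/EM"],
               100)
})
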