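## Pipeline orchestration: genotype TSV + concentration TSV -> diplotypes,
## curated cohort, metabolic-ratio/threshold outputs, association results,
## summary reports and a reconciling run manifest.

#' Run the full analysis pipeline
#'
#' Reads the two per-patient tables, calls and classifies diplotypes,
#' attaches them to the metabolite panel, applies the low-exposure
#' exclusion, computes the metabolic ratio, the regression-derived MR
#' cutoff, threshold/quadrant classifications, per-variant Hardy-Weinberg
#' tests and the association battery, and writes the report bundle
#' (TSV + JSON) with a manifest of input digests and stage-by-stage record
#' counts.
#'
#' @param genotype_tsv,concentration_tsv Input file paths.
#' @param outdir Output directory (created if needed).
#' @param defs An [AlleleDefinitions-class].
#' @param thresholds A [thresholdConfig()].
#' @param plan A [bonferroniPlan()].
#' @param encoding Genotype encoding for the Spearman tests.
#' @param cutoff_direction Regression direction for [deriveMRCutoff()].
#' @return (Invisibly) a list with every stage's result plus the manifest.
#' @export
runPipeline <- function(genotype_tsv, concentration_tsv, outdir,
                        defs = loadAlleleDefinitions(),
                        thresholds = thresholdConfig(),
                        plan = bonferroniPlan(),
                        encoding = "rank",
                        cutoff_direction = "mr_on_concentration") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genotypes <- readGenotypeTable(genotype_tsv, defs)
  cohort0 <- readConcentrationTable(concentration_tsv,
                                    lolr = defaultLolrBounds())

  only_g <- setdiff(genotypes$patient_id, patientIds(cohort0))
  only_c <- setdiff(patientIds(cohort0), genotypes$patient_id)
  if (length(only_g) || length(only_c)) {
    rec <- file.path(outdir, "id_reconciliation.tsv")
    write.table(
      data.frame(patient_id = c(only_g, only_c),
                 present_in = c(rep("genotypes", length(only_g)),
                                rep("concentrations", length(only_c)))),
      rec, sep = "\t", quote = FALSE, row.names = FALSE)
    stop("patient ids do not reconcile between tables (",
         length(only_g) + length(only_c), " unmatched); see ", rec)
  }

  diplotypes <- callCohortDiplotypes(genotypes, defs)
  cohort0 <- attachDiplotypes(cohort0, diplotypes)
  write.table(diplotypes, file.path(outdir, "diplotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  excl <- excludeLowExposure(cohort0)
  cohort <- excl$cohort
  writeConcentrationTable(cohort, file.path(outdir, "cohort_curated.tsv"))

  freq <- genotypeFrequencyTable(colData(cohort)$genotype,
                                 colData(cohort)$category)
  write.table(freq$by_genotype, file.path(outdir, "genotype_frequency.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarizeAnalytes(cohort)
  write.table(summ, file.path(outdir, "analyte_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  mr <- computeMR(cohort)
  zconc <- concentrations(cohort, zero_nd = TRUE)["z_endoxifen", ]
  cut <- deriveMRCutoff(mr$mr, zconc, thresholds,
                        direction = cutoff_direction)
  quad <- classifyQuadrants(zconc, mr$mr, cut$cutoff, thresholds)
  below <- belowThresholdByCategory(zconc, colData(cohort)$category,
                                    thresholds)
  conc_tab <- table(
    below = factor(zconc < thresholds$cutoff_reference_level,
                   levels = c(FALSE, TRUE)),
    mr_below = factor(mr$mr < cut$cutoff, levels = c(FALSE, TRUE)))
  conc_chi <- contingencyChisq(conc_tab)

  mr_out <- cbind(mr,
                  below_threshold = zconc < thresholds$endoxifen_threshold,
                  quadrant = quad$quadrant)
  write.table(mr_out, file.path(outdir, "metabolic_ratio.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  hwe <- hweByVariant(genotypes, defs)
  write.table(hwe, file.path(outdir, "hwe.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  assoc <- runAssociationSuite(cohort, plan = plan, encoding = encoding)
  write.table(assoc$ols, file.path(outdir, "associations_ols.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(assoc$spearman, file.path(outdir, "associations_spearman.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary_json <- list(
    thresholds = unclass(thresholds),
    bonferroni_plan = unclass(plan),
    mr_cutoff = cut,
    quadrant_counts = as.list(quad$counts),
    below_threshold_by_category = below,
    concordance_chisq = list(chi2 = conc_chi$chi2, df = conc_chi$df,
                             p_value = conc_chi$p_value),
    n_input = ncol(cohort0), n_retained = ncol(cohort),
    excluded_ids = excl$excluded_ids,
    mean_tamoxifen = excl$mean_tamoxifen)
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  outputs <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("TamoxPGx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(
      genotypes = list(path = genotype_tsv,
                       md5 = unname(tools::md5sum(genotype_tsv))),
      concentrations = list(path = concentration_tsv,
                            md5 = unname(tools::md5sum(concentration_tsv)))),
    counts = list(n_genotyped = nrow(genotypes),
                  n_panels = ncol(cohort0),
                  n_retained = ncol(cohort),
                  n_excluded_low_exposure = length(excl$excluded_ids)),
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(diplotypes = diplotypes, cohort = cohort,
                 excluded = excl, frequency = freq, summary = summ,
                 mr = mr_out, cutoff = cut, quadrants = quad,
                 below_threshold = below, hwe = hwe,
                 associations = assoc, manifest = manifest))
}

#' Write a synthetic bundle to disk
#'
#' Generates a synthetic cohort and writes the genotype TSV, concentration
#' TSV and truth table (true diplotypes, exposure factors, low-exposure
#' flags), plus a manifest with the seed and file digests, so the pipeline
#' can be exercised end-to-end from files alone.
#'
#' @param cfg A [generatorConfig()] (its \code{seed} drives determinism).
#' @param outdir Output directory.
#' @param defs An [AlleleDefinitions-class].
#' @return (Invisibly) list of written paths plus the simulation object.
#' @export
simulateBundle <- function(cfg, outdir, defs = loadAlleleDefinitions()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateCohort(cfg, defs)
  paths <- list(
    genotypes = file.path(outdir, "genotypes.tsv"),
    concentrations = file.path(outdir, "concentrations.tsv"),
    truth = file.path(outdir, "truth.tsv"))
  writeGenotypeTable(sim$genotype_calls, paths$genotypes)
  writeConcentrationTable(sim$cohort, paths$concentrations)
  truth <- merge(sim$diplotypes, sim$truth, by = "patient_id", sort = FALSE)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, n_patients = cfg$n_patients,
    null_effects = cfg$null_effects,
    files = lapply(paths, function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "simulation_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(sim = sim)))
}
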