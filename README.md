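# TamoxPGx

CYP2D6 star-allele genotyping and (Z)-endoxifen metabolic-ratio analysis
for tamoxifen therapy monitoring.

Tamoxifen must be bioactivated - chiefly by the highly polymorphic CYP2D6
enzyme - into (Z)-endoxifen, the metabolite that carries most of the drug's
anti-estrogenic effect. Patients whose steady-state plasma (Z)-endoxifen
falls below the ~5.97 ng/ml efficacy threshold may not benefit from the
standard 20 mg/day dose. TamoxPGx is for pharmacogenomics and therapeutic
drug monitoring analysts who need to ask, on a per-patient genotype +
metabolite table: *how well does CYP2D6 genotype predict failing the
endoxifen threshold, compared with measuring metabolism directly?*

The package implements, as tested reusable components:

* **Diplotype calling** - an 11-variant panel plus gene copy number is
  translated into star-allele pairs (`*1`-`*7`, `*9`, `*10`, `*17`, `*41`;
  `*5` = whole-gene deletion via copy number; duplications flagged) by
  exhaustive consistent-pair enumeration with parsimony/priority
  tie-breaking; ambiguous alternatives are reported, never dropped.
* **Phenotype classification** - seven ordered metabolizer categories
  `PM/PM < IM/PM < IM/IM < EM/PM < EM/IM < EM/EM < EM/UM`.
* **Panel curation** - 13 analytes (two isobaric pairs carried as summed
  analytes) with quantitation statuses (`quantified`,
  `estimated_below_lolr`, `not_detected`) and the 10%-of-mean-tamoxifen
  low-exposure exclusion, in a `SummarizedExperiment`-based container.
* **Metabolic ratio** - MR = (Z)-endoxifen / sum of the other 12 measured
  compounds; the MR cutoff corresponding to the 6 ng/ml level is derived
  by simple linear regression (default cutoff lands at ~0.0146), and
  patients are classified into concordance quadrants.
* **Association battery** - Hardy-Weinberg chi-square per variant,
  indicator-variable OLS contrasts against the EM/EM reference with
  Bonferroni control at 0.05/72 = 6.9e-4, Spearman rank correlation with
  AS 89 p-values (exact permutation for n <= 9), and contingency
  chi-square.
* **Synthetic cohort generator** - Hardy-Weinberg genotypes and
  genotype-conditional log-normal concentrations calibrated to the
  published cohort summary, so the whole pipeline runs and is tested
  without patient-level data.

## Worked example

```r
library(TamoxPGx)

cfg <- generatorConfig(seed = 1)       # study conditions: n = 285
sim <- simulateCohort(cfg)
coh <- excludeLowExposure(sim$cohort)$cohort
coh
#> TamoxifenCohort: 279 patients x 13 analytes
#>   not detected: 380 | estimated below LOLR: 424
#>   categories: PM/PM=23 IM/PM=19 IM/IM=0 EM/PM=80 EM/IM=40 EM/EM=95 EM/UM=22

mr  <- computeMR(coh)
z   <- concentrations(coh, zero_nd = TRUE)["z_endoxifen", ]
cut <- deriveMRCutoff(mr$mr, z)
signif(cut$cutoff, 3)
#> [1] 0.0147
classifyQuadrants(z, mr$mr, cut$cutoff)$counts
#>       both_above       both_below low_conc_high_mr high_conc_low_mr
#>               84              152               24               19

assoc <- runAssociationSuite(coh)
subset(assoc$spearman, outcome %in% c("z_endoxifen", "mr_z_endoxifen"))
#>           outcome     r r_squared  p_value   n      method
#>       z_endoxifen 0.668     0.446 9.01e-29 279 as89_approx
#>    mr_z_endoxifen 0.744     0.554 2.30e-35 279 as89_approx
```

Six of 285 simulated patients fall below 10% of the mean tamoxifen level
and are excluded, leaving 279. The regression-derived MR cutoff (0.0147)
translates the 6 ng/ml endoxifen threshold into ratio units; 236 of 279
patients (84.6%) are concordant between the two classifications. The
metabolic ratio is more strongly genotype-determined (r^2 = 0.55) than
the raw concentration (r^2 = 0.45) because shared exposure variability
cancels in the ratio - the key argument for monitoring metabolism rather
than genotype alone.

A command-line front end with `simulate`, `call-genotypes`, `curate`,
`mr`, `associate` and `run-all` subcommands ships in
`inst/cli/tamoxpgx.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","tamoxpgx.R",package="TamoxPGx"))')" \
    simulate --n 285 --seed 1 --out bundle/
```

## Documentation

The methods vignette (`vignettes/tamoxifen-cyp2d6-methods.Rmd`) describes
the calling model, the curation and threshold rules, the statistical
battery, the generator's calibration and its deliberate simplifications,
and known limitations (including the anti-conservativeness of the t-based
battery for very small skewed genotype groups).
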