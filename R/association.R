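## Genotype--concentration association battery: Hardy-Weinberg chi-square,
## indicator-variable OLS contrasts against EM/EM, Spearman correlation with
## AS 89 p-values, and contingency chi-square.

#' Bonferroni plan for the association battery
#'
#' The family-wise significance threshold for 12 outcomes (10 metabolite
#' concentrations plus 2 metabolic ratios) tested across 6 non-reference
#' genotype groups: alpha / (12 x 6) = 0.05/72, i.e. about 6.9e-4.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_outcomes Number of outcomes (default 12).
#' @param n_groups Number of non-reference genotype groups (default 6).
#' @return List of class \code{BonferroniPlan} with the per-test
#'   \code{threshold}.
#' @export
#' @examples
#' bonferroniPlan()$threshold   # 0.05/72
bonferroniPlan <- function(alpha = 0.05, n_outcomes = 12, n_groups = 6) {
  stopifnot(alpha > 0, n_outcomes >= 1, n_groups >= 1)
  structure(list(alpha = alpha, n_outcomes = n_outcomes,
                 n_groups = n_groups,
                 threshold = alpha / (n_outcomes * n_groups)),
            class = "BonferroniPlan")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against the expectation under Hardy-Weinberg proportions at the allele
#' frequencies estimated from the same counts. No continuity correction. A
#' monomorphic variant returns chi-square 0 and p = 1 by convention.
#'
#' @param hom_ref,het,hom_alt Genotype counts.
#' @return List with \code{chi2}, \code{df} (1), \code{p_value},
#'   \code{observed} and \code{expected} counts.
#' @export
#' @examples
#' hweChisq(25, 50, 25)  # exact HW proportions: chi2 = 0, p = 1
#' hweChisq(30, 40, 30)  # chi2 = 4
hweChisq <- function(hom_ref, het, hom_alt) {
  obs <- c(hom_ref = hom_ref, het = het, hom_alt = hom_alt)
  n <- sum(obs)
  if (n <= 0) stop("no genotype observations")
  p <- (2 * obs[["hom_ref"]] + obs[["het"]]) / (2 * n)
  if (p %in% c(0, 1))  # monomorphic: model saturates, no departure testable
    return(list(chi2 = 0, df = 1L, p_value = 1, observed = obs,
                expected = obs))
  expct <- n * c(hom_ref = p^2, het = 2 * p * (1 - p),
                 hom_alt = (1 - p)^2)
  chi2 <- sum((obs - expct)^2 / expct)
  list(chi2 = chi2, df = 1L, p_value = pchisq(chi2, 1, lower.tail = FALSE),
       observed = obs, expected = expct)
}

#' Hardy-Weinberg tests for a genotype table
#'
#' Applies [hweChisq()] to every panel variant of a genotype call table.
#' Only diploid patients (copy number 2) contribute: with a deleted or
#' duplicated gene the two-allele genotype is not observed. \code{./.}
#' calls are dropped per variant.
#'
#' @param genotypes data.frame as read by [readGenotypeTable()].
#' @param defs An [AlleleDefinitions-class] object.
#' @return data.frame with one row per variant: counts, \code{chi2},
#'   \code{p_value}.
#' @export
hweByVariant <- function(genotypes, defs = loadAlleleDefinitions()) {
  panel <- panelVariants(defs)
  dip <- genotypes[genotypes$copy_number == 2, , drop = FALSE]
  rows <- lapply(panel, function(v) {
    gt <- dip[[v]]
    gt <- gt[gt != "./."]
    st <- gtToState(gt)
    h <- hweChisq(sum(st == "hom_ref"), sum(st == "het"),
                  sum(st == "hom_alt"))
    data.frame(variant = v, hom_ref = h$observed[["hom_ref"]],
               het = h$observed[["het"]], hom_alt = h$observed[["hom_alt"]],
               chi2 = h$chi2, p_value = h$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Indicator-variable OLS contrasts against the EM/EM reference
#'
#' Fits, by ordinary least squares, an outcome on metabolizer-category
#' indicator variables with EM/EM as the reference level, so the intercept
#' is the EM/EM mean and each coefficient is that group's mean difference
#' from EM/EM. Two-sided Student t p-values on the coefficients;
#' significance at the Bonferroni plan's per-test threshold.
#'
#' @param outcome Numeric vector.
#' @param category Character or factor of metabolizer categories.
#' @param plan A [bonferroniPlan()].
#' @param reference Reference category (default \code{"EM/EM"}).
#' @return List with \code{reference_mean}, \code{residual_df} and
#'   \code{contrasts}, a data.frame (one row per non-reference group
#'   present): \code{group}, \code{n}, \code{coefficient},
#'   \code{standard_error}, \code{t_statistic}, \code{p_value},
#'   \code{significant}.
#' @export
#' @examples
#' indicatorOLS(c(7, 8, 9, 1, 2, 3),
#'              rep(c("EM/EM", "PM/PM"), each = 3))$contrasts
indicatorOLS <- function(outcome, category, plan = bonferroniPlan(),
                         reference = "EM/EM") {
  stopifnot(length(outcome) == length(category))
  f <- factor(as.character(category),
              levels = c(reference, setdiff(CATEGORY_LEVELS, reference)))
  f <- droplevels(f)
  if (anyNA(f)) stop("unknown category label(s)")
  if (!reference %in% levels(f) || sum(f == reference) == 0)
    stop("reference group '", reference, "' is empty")
  if (nlevels(f) < 2) stop("need at least two groups")
  if (isTRUE(all(outcome == outcome[1])))
    stop("outcome constant across all groups: zero residual variance")
  fit <- lm(outcome ~ f)
  sm <- summary(fit)$coefficients
  groups <- levels(f)[-1]
  rows <- data.frame(
    group = groups,
    n = as.integer(table(f)[groups]),
    coefficient = sm[-1, "Estimate"],
    standard_error = sm[-1, "Std. Error"],
    t_statistic = sm[-1, "t value"],
    p_value = sm[-1, "Pr(>|t|)"],
    stringsAsFactors = FALSE)
  rows$significant <- rows$p_value < plan$threshold
  rownames(rows) <- NULL
  list(reference_mean = unname(coef(fit)[1]),
       residual_df = fit$df.residual, contrasts = rows)
}

## AS 89 (Best & Roberts 1975) Edgeworth expansion for the upper tail
## P(S >= s) of Spearman's S = sum of squared rank differences under the
## null. Accurate for n >= 10; the exact lattice distribution is used below
## that.
as89UpperTail <- function(s, n) {
  b <- 1 / n
  x <- (6 * (s - 1) * b / (n * n - 1) - 1) * sqrt(n - 1)
  y <- x * x
  poly <- 0.2274 + 0.2531 * b + 0.1745 * b^2 +
    y * (-0.0758 + 0.1033 * b + 0.3932 * b^2) +
    y^2 * (-0.0879 * b - 0.0151 * b^2) +
    y^3 * (0.0072 * b - 0.0831 * b^2) +
    y^4 * 0.0131 * b^2 -
    y^5 * 0.00046 * b^2
  lead <- pnorm(x, lower.tail = FALSE)
  pv <- x * b * exp(-y / 2) * poly + lead
  ## far in the tail the Edgeworth polynomial can overwhelm the leading
  ## normal term (and turn the value negative); the series has left its
  ## validity region there, so fall back to the leading term
  if (pv <= 0) pv <- lead
  min(1, pv)
}

## exact permutation distribution of S for small n: all n! rank orderings
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(sub + (sub >= k), rep(k, nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

exactSpearmanTwoSided <- function(s, n, ranks_x) {
  perms <- allPermutations(n)
  svals <- colSums((t(perms) - ranks_x)^2)
  p_le <- mean(svals <= s)
  p_ge <- mean(svals >= s)
  min(1, 2 * min(p_le, p_ge))
}

#' Spearman rank correlation with AS 89 p-values
#'
#' Computes Spearman's r from midranks and a two-sided p-value for the null
#' of no association. For n of at most 9 with untied data the exact
#' permutation distribution of S (the sum of squared rank differences) is
#' enumerated; otherwise the AS 89 Edgeworth tail approximation is used
#' (applied, under ties, to the S value implied by the midrank correlation).
#' The smaller tail is doubled and capped at 1.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List of class \code{SpearmanResult}: \code{r}, \code{r_squared},
#'   \code{p_value}, \code{n}, \code{S}, \code{method} (\code{"exact"} or
#'   \code{"as89_approx"}).
#' @export
#' @examples
#' spearmanAS89(1:10, (1:10)^2)   # r = 1
spearmanAS89 <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input vector: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  ties <- max(anyDuplicated(x), anyDuplicated(y)) > 0
  ## S on the untied lattice; with midrank ties this is the equivalent S
  ## implied by r (the AS 89 statistic's scale)
  s <- (1 - r) * (n^3 - n) / 6
  if (!ties && n <= 9) {
    p <- exactSpearmanTwoSided(sum((rx - ry)^2), n, rx)
    method <- "exact"
  } else {
    ## the distribution of S is symmetric about its mean: the lower tail is
    ## the upper tail of the reflected statistic (numerically stable for
    ## strong positive correlations)
    p <- if (s > (n^3 - n) / 6) as89UpperTail(s, n)
         else as89UpperTail((n^3 - n) / 3 - s, n)
    p <- min(1, 2 * p)
    method <- "as89_approx"
  }
  structure(list(r = r, r_squared = r^2, p_value = p, n = n, S = s,
                 method = method),
            class = "SpearmanResult")
}

#' Pearson chi-square on a contingency table
#'
#' Standard Pearson chi-square without continuity correction, plus a
#' low-expected-count warning flag (any expected cell below 1).
#'
#' @param tab Matrix of counts (2 x k for the threshold-by-genotype use).
#' @return List with \code{chi2}, \code{df}, \code{p_value},
#'   \code{expected}, \code{low_expected} flag.
#' @export
#' @examples
#' contingencyChisq(matrix(c(90, 10, 10, 90), 2))
contingencyChisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all row and column sums must be positive")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected,
       low_expected = any(ct$expected < 1))
}

#' Encode metabolizer categories as an ordinal genotype variable
#'
#' Two encodings are provided because the choice is a modelling convention:
#' \code{"rank"} (default) is the fixed category rank 0..6 (PM/PM lowest,
#' EM/UM highest); \code{"activity_score"} counts functional alleles (EM =
#' 1, IM = 0.5, PM = 0 per allele, +1 for a duplication), requiring allele
#' columns.
#'
#' @param category Character or factor of categories.
#' @param encoding \code{"rank"} or \code{"activity_score"}.
#' @param diplotypes Optional data.frame with \code{allele_a},
#'   \code{allele_b}, \code{duplicated} (needed for the activity score).
#' @param defs An [AlleleDefinitions-class] (activity classes for the
#'   score).
#' @return Numeric vector.
#' @export
encodeGenotype <- function(category, encoding = c("rank", "activity_score"),
                           diplotypes = NULL,
                           defs = loadAlleleDefinitions()) {
  encoding <- match.arg(encoding)
  if (encoding == "rank") {
    f <- factor(as.character(category), levels = CATEGORY_LEVELS)
    if (anyNA(f)) stop("unknown category label(s)")
    return(as.numeric(f) - 1)
  }
  if (is.null(diplotypes))
    stop("activity_score encoding needs the diplotype table")
  act <- alleleActivity(defs)
  sc <- c(EM = 1, IM = 0.5, PM = 0)
  unname(sc[act[diplotypes$allele_a]] + sc[act[diplotypes$allele_b]] +
           as.numeric(diplotypes$duplicated))
}

#' Default association outcomes
#'
#' The 12 outcomes of the association battery: the 10 metabolite
#' concentrations (the 12 non-tamoxifen analytes minus the two essentially
#' undetectable trace compounds, (E)-endoxifen and (Z)-alpha-OH-Tam) plus
#' the two metabolic ratios.
#'
#' @return Character vector of outcome ids; MR outcomes are prefixed
#'   \code{"mr_"}.
#' @export
defaultOutcomes <- function() {
  conc <- setdiff(ANALYTE_IDS, c("tamoxifen", "e_endoxifen", "z_aoh_tam"))
  c(conc, "mr_z_endoxifen", "mr_z_4oh_tam")
}

#' Run the genotype--concentration association battery
#'
#' For every outcome: an indicator-OLS contrast set against EM/EM under the
#' Bonferroni plan, and a Spearman correlation (AS 89 p-value) against the
#' ordinal genotype encoding. Outcome values use the not-detected-as-zero
#' convention; MR outcomes are computed with [computeMR()]. Unavailable
#' outcomes are reported as skipped, not fatal.
#'
#' @param x A [TamoxifenCohort-class] with categories attached.
#' @param outcomes Character vector of outcome ids (see
#'   [defaultOutcomes()]).
#' @param plan A [bonferroniPlan()].
#' @param encoding Genotype encoding for the Spearman test (see
#'   [encodeGenotype()]).
#' @return List of class \code{AssociationSuite}: \code{ols} (data.frame of
#'   contrasts, one row per outcome x group), \code{spearman} (one row per
#'   outcome), \code{plan}, \code{skipped}.
#' @export
runAssociationSuite <- function(x, outcomes = defaultOutcomes(),
                                plan = bonferroniPlan(),
                                encoding = "rank") {
  category <- phenotypeCategories(x)
  if (is.null(category))
    stop("cohort has no metabolizer categories attached")
  dt <- as.data.frame(colData(x))
  g <- encodeGenotype(category, encoding,
                      diplotypes = if (encoding == "activity_score") dt)
  conc <- concentrations(x, zero_nd = TRUE)
  ols_rows <- list(); sp_rows <- list(); skipped <- character()
  for (oc in outcomes) {
    y <- if (startsWith(oc, "mr_")) {
      num <- sub("^mr_", "", oc)
      if (!num %in% ANALYTE_IDS) NULL else computeMR(x, num)$mr
    } else if (oc %in% rownames(conc)) conc[oc, ] else NULL
    if (is.null(y)) { skipped <- c(skipped, oc); next }
    fit <- indicatorOLS(y, category, plan)
    ols_rows[[oc]] <- cbind(outcome = oc, fit$contrasts,
                            reference_mean = fit$reference_mean,
                            stringsAsFactors = FALSE)
    sp <- spearmanAS89(g, y)
    sp_rows[[oc]] <- data.frame(outcome = oc, r = sp$r,
                                r_squared = sp$r_squared,
                                p_value = sp$p_value, n = sp$n,
                                method = sp$method, stringsAsFactors = FALSE)
  }
  ols <- if (length(ols_rows)) do.call(rbind, ols_rows) else
    data.frame(outcome = character())
  sp <- if (length(sp_rows)) do.call(rbind, sp_rows) else
    data.frame(outcome = character())
  rownames(ols) <- rownames(sp) <- NULL
  structure(list(ols = ols, spearman = sp, plan = plan, skipped = skipped,
                 encoding = encoding),
            class = "AssociationSuite")
}
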