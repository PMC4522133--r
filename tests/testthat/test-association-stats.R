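test_that("Hardy-Weinberg chi-square matches hand computation", {
  r <- hweChisq(25, 50, 25)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  r <- hweChisq(30, 40, 30)
  expect_equal(unname(r$expected), c(25, 50, 25))
  expect_equal(r$chi2, 4)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE))

  r <- hweChisq(100, 0, 100)
  expect_lt(r$p_value, 0.001)

  mono <- hweChisq(42, 0, 0)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p_value, 1)
})

test_that("Hardy-Weinberg test is invariant under allele-label swap", {
  set.seed(4)
  for (k in 1:20) {
    n <- sample(20:400, 3)
    a <- hweChisq(n[1], n[2], n[3])
    b <- hweChisq(n[3], n[2], n[1])
    expect_equal(a$chi2, b$chi2)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("indicator-OLS coefficients are group-mean differences", {
  r <- indicatorOLS(c(7, 8, 9, 1, 2, 3),
                    rep(c("EM/EM", "PM/PM"), each = 3))
  expect_equal(r$reference_mean, 8)
  expect_equal(r$contrasts$coefficient, -6)

  ## closed-form identity on random inputs
  set.seed(12)
  for (k in 1:25) {
    groups <- sample(categoryLevels(),
                     sample(3:7, 1))
    groups <- union(groups, "EM/EM")
    cat_v <- sample(groups, 120, replace = TRUE)
    ## guarantee every group non-empty
    cat_v[seq_along(groups)] <- groups
    y <- rnorm(120, mean = as.numeric(factor(cat_v)))
    r <- indicatorOLS(y, cat_v)
    ref <- mean(y[cat_v == "EM/EM"])
    expect_equal(r$reference_mean, ref, tolerance = 1e-10)
    for (i in seq_len(nrow(r$contrasts))) {
      g <- r$contrasts$group[i]
      expect_equal(r$contrasts$coefficient[i],
                   mean(y[cat_v == g]) - ref, tolerance = 1e-10)
    }
  }

  ## a single-observation group is retained
  r <- indicatorOLS(c(5, 6, 7, 2), c("EM/EM", "EM/EM", "EM/EM", "PM/PM"))
  expect_equal(r$contrasts$n[r$contrasts$group == "PM/PM"], 1L)
  expect_equal(r$residual_df, 2)

  expect_error(indicatorOLS(rep(3, 6), rep(c("EM/EM", "PM/PM"), 3)),
               "constant")
  expect_error(indicatorOLS(1:3, rep("PM/PM", 3)), "reference")
  ## all groups identical values -> zero coefficients (not an error)
  r <- indicatorOLS(c(1, 2, 3, 1, 2, 3), rep(c("EM/EM", "PM/PM"), each = 3))
  expect_equal(r$contrasts$coefficient, 0)
  expect_false(any(r$contrasts$significant))
})

test_that("the Bonferroni plan reproduces the 0.05/72 threshold", {
  plan <- bonferroniPlan()
  expect_equal(plan$threshold, 0.05 / 72)
  expect_equal(signif(plan$threshold, 2), 6.9e-4)
})

test_that("Spearman exact p equals the brute-force permutation p", {
  perm_oracle <- function(x, y) {
    rx <- rank(x)
    perms <- matrix(unlist(combinat_perms(length(y))), ncol = length(y),
                    byrow = TRUE)
    r_obs <- cor(rx, rank(y))
    rs <- apply(perms, 1, function(p) cor(rx, p))
    min(1, 2 * min(mean(rs <= r_obs + 1e-12),
                   mean(rs >= r_obs - 1e-12)))
  }
  ## independent recursive permutation generator
  combinat_perms <- function(n) {
    if (n == 1) return(list(1))
    out <- list()
    for (p in combinat_perms(n - 1))
      for (k in seq_len(n))
        out[[length(out) + 1]] <- append(p, n, after = k - 1)
    out
  }
  set.seed(6)
  for (n in 4:7) {
    for (rep in 1:4) {
      x <- sample(100, n); y <- sample(100, n)
      r <- spearmanAS89(x, y)
      expect_equal(r$method, "exact")
      expect_equal(r$p_value, perm_oracle(x, y), tolerance = 1e-12)
      expect_equal(r$r_squared, r$r^2)
    }
  }
  ## the worked n = 5 example
  r <- spearmanAS89(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$r, 0.8)
  expect_equal(r$p_value, perm_oracle(1:5, c(2, 1, 4, 3, 5)))
})

test_that("Spearman AS 89 branch agrees with the base-R implementation", {
  set.seed(9)
  for (n in c(12, 25, 60, 150)) {
    for (rep in 1:8) {
      x <- rnorm(n); y <- x * runif(1, -1, 1) + rnorm(n)
      mine <- spearmanAS89(x, y)
      expect_equal(mine$method, "as89_approx")
      ct <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = TRUE))
      expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(mine$p_value, ct$p.value,
                   tolerance = max(1e-8, 1e-3 * ct$p.value))
    }
  }
})

test_that("Spearman handles ties, monotone data and degenerate input", {
  r <- spearmanAS89(1:10, (1:10)^2)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  ## tied ordinal predictor: midranks, AS 89 approximation
  set.seed(3)
  g <- sample(0:6, 40, replace = TRUE)
  y <- g + rnorm(40)
  r <- spearmanAS89(g, y)
  expect_equal(r$method, "as89_approx")
  expect_equal(r$r, cor(g, y, method = "spearman"))
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_lt(r$p_value, 1e-4)
  expect_error(spearmanAS89(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearmanAS89(1:2, 1:2), "at least 3")
})

test_that("contingency chi-square matches hand arithmetic", {
  r <- contingencyChisq(matrix(c(50, 50, 50, 50), 2))
  expect_equal(r$chi2, 0)
  r <- contingencyChisq(matrix(c(90, 10, 10, 90), 2))
  expect_equal(r$chi2, 128)
  expect_equal(r$df, 1)
  expect_lt(r$p_value, 0.001)
  expect_false(r$low_expected)
  ## perfectly concordant table with tiny margins flags low expectation
  r <- contingencyChisq(matrix(c(1, 0, 0, 99), 2))
  expect_true(r$low_expected)
  expect_error(contingencyChisq(matrix(c(0, 0, 5, 5), 2)), "positive")
})

test_that("the genotype encodings are ordered as documented", {
  expect_equal(encodeGenotype(categoryLevels()), 0:6)
  dt <- data.frame(allele_a = c("*1", "*4", "*1"),
                   allele_b = c("*1", "*4", "*41"),
                   duplicated = c(TRUE, FALSE, FALSE))
  sc <- encodeGenotype(c("EM/UM", "PM/PM", "EM/IM"),
                       encoding = "activity_score", diplotypes = dt,
                       defs = DEFS)
  expect_equal(sc, c(3, 0, 1.5))
})

test_that("the association suite reports outcomes, skips and the plan", {
  sim <- simulateCohort(generatorConfig(n_patients = 60, seed = 21))
  coh <- sim$cohort
  res <- runAssociationSuite(coh)
  expect_equal(sort(unique(res$ols$outcome)), sort(defaultOutcomes()))
  expect_equal(nrow(res$spearman), 12)
  expect_length(res$skipped, 0)
  res2 <- runAssociationSuite(coh, outcomes = c("z_endoxifen", "no_such"))
  expect_equal(res2$skipped, "no_such")
  res3 <- runAssociationSuite(coh, outcomes = character(0))
  expect_equal(nrow(res3$ols), 0)
  ## activity-score encoding runs end to end
  res4 <- runAssociationSuite(coh, outcomes = "z_endoxifen",
                              encoding = "activity_score")
  expect_gt(res4$spearman$r, 0)
})
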