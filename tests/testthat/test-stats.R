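# Statistical pipeline: normality gate, two-group and six-group tests,
# correlation table, interaction scan, adjusted regression, and the
# orchestrated report.

test_that("normality gate passes normal data and ln-fixes lognormal data", {
  set.seed(21)
  x <- rnorm(500)
  g <- normality_gate(x)
  expect_true(g$is_normal)
  expect_equal(g$transform_applied, "none")
  expect_identical(g$transformed_x, x)

  y <- exp(rnorm(500, sd = 1))
  gy <- normality_gate(y)
  expect_equal(gy$transform_applied, "ln")
  expect_true(gy$is_normal)
  expect_equal(gy$transformed_x, log(y))

  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "at least 3")
  # deterministic subsampling keeps the gate defined beyond n = 5000
  expect_true(normality_gate(rnorm(6000))$is_normal)
})

test_that("two-group comparison picks the gated test and detects shifts", {
  # exactly tied duplicated samples: no evidence of a difference
  x <- rep(c(1, 2, 3, 10, 20, 50), 10)
  g <- rep(c("a", "b"), each = 30)
  same <- compare_two_groups(c(x[1:30], x[1:30]), g)
  expect_gt(same$p, 0.99)

  set.seed(22)
  xs <- c(rnorm(50), rnorm(50, mean = 5))
  gs <- rep(c("a", "b"), each = 50)
  shift <- compare_two_groups(xs, gs)
  expect_lt(shift$p, 1e-6)
  expect_true(shift$test %in% c("t", "Mann-Whitney"))

  # categorical variables go through the chi-squared test
  set.seed(23)
  cat_x <- factor(sample(c("yes", "no"), 200, TRUE, prob = c(0.5, 0.5)))
  cat_g <- rep(c("a", "b"), 100)
  chis <- compare_two_groups(cat_x, cat_g)
  expect_equal(chis$test, "chi-squared")
  expect_true(chis$p > 0 && chis$p <= 1)

  expect_error(compare_two_groups(1:5, rep("a", 5)), "two non-empty")
})

test_that("skewed variables are compared after ln transform under the gate", {
  set.seed(23)
  x <- exp(c(rnorm(80), rnorm(80, 0.8)))
  g <- rep(c("a", "b"), each = 80)
  res <- compare_two_groups(x, g)
  expect_equal(res$transform, "ln")
  expect_equal(res$test, "t")
  expect_lt(res$p, 0.01)
})

test_that("isoform comparison applies the 0.05/15 Bonferroni threshold", {
  expect_equal(bonferroni_alpha(6), 0.05 / 15)
  expect_equal(round(bonferroni_alpha(6), 4), 0.0033)

  set.seed(25)
  dip <- sample_diplotypes(600, seed = 25)
  x <- rnorm(600)
  null_res <- compare_isoform_groups(x, dip)
  expect_equal(null_res$alpha_pairwise, 0.05 / 15)
  expect_equal(nrow(null_res$pairwise), 15)
  expect_true(null_res$kw_p > 0 && null_res$kw_p <= 1)

  # one strongly shifted group fires exactly its five pairwise flags
  x_shift <- x + ifelse(dip == "Gc2/Gc2", 10, 0)
  res <- compare_isoform_groups(x_shift, dip)
  expect_lt(res$kw_p, 1e-10)
  hit <- res$pairwise$group1 == "Gc2/Gc2" | res$pairwise$group2 == "Gc2/Gc2"
  expect_true(all(res$pairwise$significant[hit]))
  expect_false(any(res$pairwise$significant[!hit]))

  # unordered labels are normalized before grouping
  res2 <- compare_isoform_groups(x_shift, sub("Gc1f/Gc2", "Gc2/Gc1f", dip))
  expect_equal(res2$kw_p, res$kw_p)

  expect_error(compare_isoform_groups(rnorm(20),
                                      rep("Gc1f/Gc1f", 20)), "Gc2/Gc2")
})

test_that("correlation table handles identities, transforms and missingness", {
  d <- data.frame(x = c(1:10), y = -(1:10), z = exp(seq(0.1, 1, 0.1)))
  tab <- correlation_table(d, "x", c("x", "y"))
  expect_equal(tab$r, c(1, -1))
  # ln transform linearizes an exponential relation
  tl <- correlation_table(d, "x", "z", transform = "z")
  expect_equal(tl$r, 1, tolerance = 1e-12)
  # generator structure: iPTH runs against total 25OHD
  tc <- correlation_table(big_cohort, "ipth_pg_ml", "total_25ohd_ng_ml")
  expect_lt(tc$r, 0)
  expect_equal(tc$n, nrow(big_cohort))
  expect_error(correlation_table(d, "nope", "x"), "not found")
})

test_that("interaction scan detects the injected opposite-sign slopes", {
  res <- interaction_scan(big_panel, "bmc_tb_z", "total_25ohd_ng_ml")
  expect_lt(res$p_interaction, 0.05)
  expect_lt(res$beta_interaction, 0)  # slope drops in overweight/obese
  one_cat <- big_panel[big_panel$bmi_category == "normal", ]
  expect_error(interaction_scan(one_cat, "bmc_tb_z", "total_25ohd_ng_ml"),
               "BMI groups")
})

test_that("adjusted regression is exact on noiseless data and flags collinearity", {
  set.seed(26)
  n <- 80
  d <- data.frame(age_yr = runif(n, 5, 13), sex = sample(c("M", "F"), n, TRUE),
                  fm_z = rnorm(n), lm_z = rnorm(n), x = rnorm(n))
  d$y <- 2 + 0.5 * d$x
  # base R warns about the intentionally perfect fit; the numbers are exact
  fit <- suppressWarnings(adjusted_regression(d, "y", "x"))
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$se, 1e-10)
  expect_false(fit$vif_flag)
  expect_true(all(fit$vif >= 1, na.rm = TRUE))

  # a near-duplicate of the predictor inflates VIF past the threshold
  d$y2 <- 2 + 0.5 * d$x + rnorm(n)
  d$x_dup <- d$x + rnorm(n, sd = 1e-4)
  dup <- adjusted_regression(d, "y2", "x",
                             covariates = c("x_dup", "age_yr", "sex"))
  expect_true(dup$vif_flag)

  expect_error(adjusted_regression(d[1:3, ], "y", "x"), "complete cases")
})

test_that("adjusted regression recovers the injected normal-weight slope", {
  nw <- big_panel[big_panel$bmi_category == "normal", ]
  fit <- adjusted_regression(nw, "bmc_tb_z", "total_25ohd_ng_ml")
  expect_true(fit$ci[1] <= 0.030 && 0.030 <= fit$ci[2])
  expect_lt(fit$p, 0.001)
  expect_equal(fit$r_squared, 0.6, tolerance = 0.1)
})

test_that("the orchestrated report is complete, stratified and deterministic", {
  expect_error(run_table_suite(study_panel[0, ]), "empty")
  expect_error(run_table_suite(study_cohort), "derive_panel")

  rep1 <- run_table_suite(study_panel)
  expect_s3_class(rep1, "vitd_report")
  expect_gt(nrow(rep1$comparisons), 0)
  expect_gt(nrow(rep1$correlations), 0)
  expect_gt(nrow(rep1$interactions), 0)
  expect_gt(nrow(rep1$regressions), 0)
  # stratified cells never use more rows than the stratum holds
  n_normal <- sum(study_panel$bmi_category == "normal", na.rm = TRUE)
  expect_true(all(rep1$regressions$n[rep1$regressions$stratum == "normal"]
                  <= n_normal))
  # identical input -> identical report
  rep2 <- run_table_suite(study_panel)
  expect_identical(rep1, rep2)
})
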