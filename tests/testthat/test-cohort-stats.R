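test_that("paired t matches the hand formula and rejects degenerate input", {
  # differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.464, df 2
  r <- paired_t(c(3, 4, 6), c(2, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(round(r$statistic, 3), 3.464)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-abs(r$statistic), 2), tolerance = 1e-12)
  # x = y with varying differences is the null identity; constant-zero
  # differences are degenerate
  x <- c(1, 2, 3, 4)
  expect_error(paired_t(x, x), "degenerate")
  r0 <- paired_t(x, x + c(-1, 1, -1, 1))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_error(paired_t(1:2, 2:3), "3 complete pairs")
})

test_that("pearson_r matches the product-moment formula", {
  expect_equal(pearson_r(1:5, 1:5)$estimate, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$estimate, -1)
  r <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$estimate, 0.8, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_error(pearson_r(1:4, rep(2, 4)), "zero variance")
})

test_that("independent t and one-way ANOVA match brute-force oracles", {
  r <- independent_t(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$statistic, oracle_pooled_t(1:3, 4:6), tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:10) {
    g <- factor(rep(c("a", "b", "c"), times = c(8, 10, 7)))
    v <- rnorm(length(g)) + (g == "b") * runif(1, 0, 2)
    a <- oneway_anova(v, g)
    expect_equal(a$statistic, oracle_anova_F(v, g), tolerance = 1e-10)
    expect_equal(a$df, c(2, 22))
    x <- rnorm(12); h <- rep(c("u", "v"), 6)
    expect_equal(independent_t(x, h)$statistic,
                 oracle_pooled_t(x[h == "u"], x[h == "v"]), tolerance = 1e-10)
  }
  same <- oneway_anova(rep(c(1, 2), 6), rep(c("a", "b"), each = 6))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_error(independent_t(1:6, rep("a", 6)), "2 groups")
})

test_that("a single-binary-predictor GLM is the pooled t-test", {
  set.seed(2)
  d <- data.frame(y = rnorm(60), g = factor(rep(c("Low", "High"), 30),
                                            levels = c("Low", "High")))
  d$y[d$g == "High"] <- d$y[d$g == "High"] - 0.8
  g <- fit_glm(y ~ g, d, reference = list(g = "Low"))
  tt <- independent_t(d$y, d$g)
  m <- tapply(d$y, d$g, mean)
  expect_equal(g$coefficients$estimate[2L], unname(m["High"] - m["Low"]),
               tolerance = 1e-12)
  expect_equal(g$coefficients$p_value[2L], tt$p_value, tolerance = 1e-12)
  # statistic^2 equals the ANOVA/GLM F for the term
  f <- g$eta_squared / (1 - g$eta_squared) * (nrow(d) - 2)
  expect_equal(unname(f), tt$statistic^2, tolerance = 1e-10)
})

test_that("balanced two-factor GLM reproduces the cell-means oracle", {
  d <- expand.grid(a = factor(c("a1", "a2")), b = factor(c("b1", "b2", "b3")),
                   rep = 1:5)
  set.seed(3)
  d$y <- 2 + (d$a == "a2") * 1.5 + (d$b == "b2") * 0.7 -
    (d$b == "b3") * 0.4 + rnorm(nrow(d), 0, 0.5)
  g <- fit_glm(y ~ a + b, d, reference = list(a = "a1", b = "b1"))
  X <- cbind(1, d$a == "a2", d$b == "b2", d$b == "b3")
  expect_equal(g$coefficients$estimate, oracle_ls_coef(X, d$y),
               tolerance = 1e-10)
  expect_true(all(g$coefficients$ci_lower <= g$coefficients$estimate &
                    g$coefficients$estimate <= g$coefficients$ci_upper))
})

test_that("reference levels are honoured and rank deficiency is named", {
  d <- data.frame(y = rnorm(20),
                  edu = factor(rep(c("Low", "Middle", "High"), length.out = 20)))
  g <- fit_glm(y ~ edu, d, reference = list(edu = "High"))
  expect_false(any(grepl("eduHigh", g$coefficients$term)))
  expect_true(any(grepl("eduLow", g$coefficients$term)))
  d$dup <- d$edu   # perfectly aliased copy
  expect_error(fit_glm(y ~ edu + dup, d), "aliased")
})

test_that("planted class contrast is recovered by t-test and adjusted GLM", {
  coh <- simulate_cohort(cohort_config(n_dyads = 4000, seed = 11))
  tt <- independent_t(coh$sensitivity_30mo, coh$depressive_class)
  # planted contrast: 4.66 - 5.30 = -0.64, attenuated toward about -0.57
  # by clipping to the 1-7 scale (the bounded instrument compresses the
  # upper tail, where the low-symptom class sits)
  expect_lt(abs((tt$means[2L] - tt$means[1L]) - (-0.64)), 0.1)
  g <- fit_glm(sensitivity_30mo ~ education + income + infant_sex +
                 depressive_class, coh,
               reference = list(education = "University", income = ">3500",
                                infant_sex = "girl",
                                depressive_class = "Low"))
  cls <- grepl("depressive_classHigh", g$coefficients$term)
  expect_lt(abs(g$coefficients$estimate[cls] - (-0.64)), 0.1)
  # no covariate effects were planted
  covs <- !cls & g$coefficients$term != "(Intercept)"
  expect_true(all(abs(g$coefficients$estimate[covs]) < 0.25))
})

test_that("the pipeline reproduces the planted cohort structure", {
  coh <- simulate_cohort(cohort_config(n_dyads = 2000, seed = 21))
  rep1 <- run_pipeline(coh)
  expect_s3_class(rep1, "cohort_report")
  # age comparison: entropy decreases (positive paired t), sensitivity flat
  ac <- rep1$age_comparison
  expect_gt(ac$t[1L], 10)
  expect_equal(ac$mean_8mo[1L], 0.87, tolerance = 0.02)
  expect_equal(ac$mean_30mo[1L], 0.79, tolerance = 0.02)
  expect_lt(abs(ac$t[2L]), 4)
  # planted correlation structure, in sign and magnitude (n = 2000, so
  # sampling error on r is about 0.022; allow 3 SE plus slight clipping
  # attenuation)
  cr <- rep1$correlations
  expect_lt(abs(cr$estimate[1L] - 0.296), 0.07)
  expect_lt(abs(cr$estimate[2L] - 0.293), 0.07)
  expect_lt(abs(cr$estimate[3L] - (-0.279)), 0.07)
  expect_lt(abs(cr$estimate[4L] - (-0.146)), 0.07)
  # class effect present on sensitivity, absent on entropy
  ct <- rep1$class_tests
  expect_gt(ct$p_value[1L], 0.01)
  expect_lt(ct$p_value[2L], 0.001)
  expect_gt(ct$estimate[2L], 0.4)   # Low - High > 0
  # diagnostic: transitions unrelated to entropy
  expect_true(all(abs(rep1$diagnostics$estimate) < 0.1))
  expect_output(print(rep1), "raw \\(unadjusted\\)")
})

test_that("pipeline runs are deterministic given the seed and writable", {
  c1 <- simulate_cohort(cohort_config(n_dyads = 600, seed = 31))
  c2 <- simulate_cohort(cohort_config(n_dyads = 600, seed = 31))
  r1 <- run_pipeline(c1)
  r2 <- run_pipeline(c2)
  expect_identical(r1$age_comparison, r2$age_comparison)
  expect_identical(r1$meta$config_hash, r2$meta$config_hash)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_report(r1, dir1)
  write_report(r2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_true(file.exists(file.path(dir1, "age_comparison.tsv")))
  expect_error(run_pipeline(c1[, 1:3]), "missing required column")
})

test_that("null cohorts give small effects and calibrated p-values", {
  set.seed(41)
  # no planted effects anywhere: class contrasts zero, correlations zero
  cfg <- cohort_config(n_dyads = 300, entropy_mean = c(0.8, 0.8),
                       entropy_sd = c(0.15, 0.15),
                       entropy_stability = 0, sensitivity_stability = 0,
                       entropy_sensitivity_r = c(0, 0),
                       sensitivity_mean = c(4, 4), sensitivity_sd = c(0.8, 0.8),
                       depressive_class_means = c(high = 4, low = 4),
                       anxiety_class_means = c(high = 4, low = 4),
                       seed = 41)
  coh <- simulate_cohort(cfg)
  rep0 <- run_pipeline(coh)
  # n = 300: 3 standard errors on a null correlation is about 0.17
  expect_true(all(abs(rep0$correlations$estimate) < 0.175))
  expect_true(all(abs(rep0$class_tests$estimate) < 0.4))
  p <- replicate(400, {
    g1 <- rnorm(25); g2 <- rnorm(25)
    independent_t(c(g1, g2), rep(c("a", "b"), each = 25))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
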