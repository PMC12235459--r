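test_that("BH adjustment matches the step-up rule and the oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:24, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone non-decreasing when re-sorted by raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.2, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.2, 1.2)), "\\(0, 1\\]")
})

test_that("distribution summary matches reference kurtosis values", {
  set.seed(23)
  nrm <- summarize_distribution(rnorm(1e6), "normal")
  expect_equal(nrm$excess_kurtosis, 0, tolerance = 0.05)
  unif <- summarize_distribution(runif(1e6), "uniform")
  expect_equal(unif$excess_kurtosis, -1.2, tolerance = 0.05)
  expect_error(summarize_distribution(c(1, 2, 3)), "at least 4")
  expect_error(summarize_distribution(rep(2, 10)), "constant")
})

test_that("a feature identical to the score recovers beta = 1", {
  set.seed(41)
  n_subj <- 12
  d <- data.frame(
    subject = rep(sprintf("S%02d", 1:n_subj), each = 5),
    visit = rep(visit_levels(), n_subj))
  d$age <- rep(round(runif(n_subj, 20, 60)), each = 5)
  d$sex <- rep(sample(c("male", "female"), n_subj, TRUE), each = 5)
  d$race <- rep(sample(c("black", "white"), n_subj, TRUE), each = 5)
  d$feature <- rnorm(nrow(d), 20, 4)
  d$score <- d$feature
  r <- fit_mixed_association(d$feature, d$score, d$age, d$sex, d$race,
                             d$subject, d$visit, "ident", "PANSS-P")
  expect_equal(r$beta, 1.0, tolerance = 1e-6)
  expect_lt(r$p_raw, 1e-10)
  expect_equal(r$direction, "+")
})

test_that("mixed-model fixed effect matches OLS when RE variances are zero", {
  set.seed(42)
  n_subj <- 30
  d <- data.frame(
    subject = rep(sprintf("S%02d", 1:n_subj), each = 5),
    visit = rep(visit_levels(), n_subj))
  d$age <- rep(round(runif(n_subj, 20, 60)), each = 5)
  d$sex <- rep(sample(c("male", "female"), n_subj, TRUE), each = 5)
  d$race <- rep(sample(c("black", "white", "other"), n_subj, TRUE), each = 5)
  d$feature <- rnorm(nrow(d))
  # realized subject and visit effects exactly zero: residuals centered
  # within both grouping factors, so REML sits on the zero boundary
  e <- rnorm(nrow(d))
  e <- e - ave(e, d$subject)
  e <- e - ave(e, d$visit)
  d$score <- 18 + 0.7 * d$feature + 0.1 * d$age +
    0.5 * (d$sex == "female") + e
  r <- fit_mixed_association(d$feature, d$score, d$age, d$sex, d$race,
                             d$subject, d$visit, "f", "PANSS-P")
  ols <- unname(coef(lm(score ~ feature + age + sex + race, d))["feature"])
  expect_equal(r$beta, ols, tolerance = 1e-3)
  expect_gt(r$partial_eta_sq, 0)
  expect_lt(r$partial_eta_sq, 1)
})

test_that("sign flip of the feature flips beta, keeps p and eta", {
  set.seed(43)
  n_subj <- 20
  d <- data.frame(
    subject = rep(sprintf("S%02d", 1:n_subj), each = 5),
    visit = rep(visit_levels(), n_subj))
  d$age <- rep(round(runif(n_subj, 20, 60)), each = 5)
  d$sex <- rep(sample(c("male", "female"), n_subj, TRUE), each = 5)
  d$race <- rep(sample(c("black", "white"), n_subj, TRUE), each = 5)
  subj_eff <- rep(rnorm(n_subj, 0, 2), each = 5)
  d$feature <- rnorm(nrow(d))
  d$score <- 20 + 0.6 * d$feature + subj_eff + rnorm(nrow(d))
  r1 <- fit_mixed_association(d$feature, d$score, d$age, d$sex, d$race,
                              d$subject, d$visit, "f", "s")
  r2 <- fit_mixed_association(-d$feature, d$score, d$age, d$sex, d$race,
                              d$subject, d$visit, "f", "s")
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-9)
  expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-9)
  expect_equal(r2$partial_eta_sq, r1$partial_eta_sq, tolerance = 1e-9)
})

test_that("zero-variance features and missing rows are handled", {
  d <- data.frame(subject = rep(c("a", "b", "c"), each = 4),
                  visit = rep(c("screening", "baseline", "day14", "day28"), 3))
  d$age <- 30; d$sex <- "male"; d$race <- "black"
  d$score <- rnorm(12, 20)
  expect_error(
    fit_mixed_association(rep(1, 12), d$score, d$age, d$sex, d$race,
                          d$subject, d$visit, "flat", "s"),
    "flat.*zero variance")
  f <- rnorm(12)
  f[1:2] <- NA
  r <- fit_mixed_association(f, d$score, d$age, d$sex, d$race,
                             d$subject, d$visit, "f", "s")
  expect_equal(r$n_dropped, 2)
  expect_equal(r$n_obs, 10)
})

test_that("demographic screen recovers perfect age correlation, skips small groups", {
  set.seed(44)
  n <- 40
  d <- data.frame(age = runif(n, 20, 60),
                  sex = sample(c("male", "female"), n, TRUE),
                  race = c(rep("black", n - 2), "white", "white"))
  d$feat_age <- 2 * d$age
  d$feat_noise <- rnorm(n)
  scr <- demographic_screen(d, c("feat_age", "feat_noise"))
  age_row <- scr[scr$feature == "feat_age" & scr$test == "age_pearson", ]
  expect_equal(age_row$estimate, 1.0, tolerance = 1e-9)
  expect_equal(age_row$r_squared, age_row$estimate^2, tolerance = 1e-12)
  race_row <- scr[scr$feature == "feat_age" & scr$test == "race_ttest", ]
  expect_true(grepl("skipped", race_row$note))
  expect_true(is.na(race_row$p))
})

test_that("sex t-test is calibrated under the null", {
  set.seed(45)
  rejections <- 0L
  for (i in 1:100) {
    n <- 60
    d <- data.frame(age = runif(n, 20, 60),
                    sex = rep(c("male", "female"), each = n / 2),
                    race = sample(c("black", "white"), n, TRUE))
    d$f <- rnorm(n) # same distribution for both sexes
    scr <- demographic_screen(d, "f")
    p <- scr$p[scr$test == "sex_ttest"]
    if (!is.na(p) && p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 10) # p > 0.05 in >= 90% of null replicates
})

test_that("baseline-averaged OLS is idempotent for identical visits", {
  set.seed(46)
  n <- 24
  subj <- sprintf("S%02d", 1:n)
  base <- data.frame(subject_id = subj, age = runif(n, 20, 60),
                     sex = sample(c("male", "female"), n, TRUE),
                     race = sample(c("black", "white"), n, TRUE),
                     f1 = rnorm(n))
  base$panss_p <- round(20 + 2 * base$f1 + rnorm(n))
  base$panss_n <- round(20 - 2 * base$f1 + rnorm(n))
  two <- rbind(transform(base, visit = "screening"),
               transform(base, visit = "baseline"))
  one <- transform(base, visit = "screening")
  r2 <- baseline_average_ols(two, "f1")
  r1 <- baseline_average_ols(one, "f1")
  expect_equal(r2$results$beta, r1$results$beta, tolerance = 1e-9)
  expect_equal(r2$n_single_visit, 0)
  expect_equal(r1$n_single_visit, n)
  expect_error(baseline_average_ols(one[1:5, ], "f1"), "at least 10")
})

test_that("suite applies per-scale FDR and reports a direction matrix", {
  spec <- cohort_spec(n_subjects = 20, seed = 101)
  ds <- generate_dataset(spec)
  ft <- extract_dataset_features(ds, identify = FALSE)
  suite <- run_association_suite(ft, ds$clinical)
  expect_equal(nrow(suite$results), 24)
  expect_true(all(suite$results$p_fdr >= suite$results$p_raw - 1e-15))
  for (sc in unique(suite$results$scale)) {
    idx <- suite$results$scale == sc
    expect_equal(suite$results$p_fdr[idx],
                 bh_fdr(suite$results$p_raw[idx]))
  }
  dm <- direction_matrix(suite)
  expect_equal(nrow(dm), 12)
  expect_true(all(c("direction_P", "direction_N") %in% names(dm)))
  # pooled scope uses one 24-test family
  pooled <- run_association_suite(ft, ds$clinical,
                                  suite_config(fdr_scope = "pooled"))
  expect_equal(pooled$results$p_fdr, bh_fdr(pooled$results$p_raw))
  # empty join errors
  bad <- ds$clinical
  bad$subject_id <- paste0("X", bad$subject_id)
  expect_error(run_association_suite(ft, bad), "zero rows")
})
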