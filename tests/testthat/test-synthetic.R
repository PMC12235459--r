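test_that("cohort sampling is deterministic and correctly sized", {
  spec <- cohort_spec(n_subjects = 10, seed = 99)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$clinical), 50)
  expect_true(all(a$clinical$panss_p >= 7 & a$clinical$panss_p <= 49))
  expect_true(all(a$clinical$visit %in% visit_levels()))
  expect_true(all(a$clinical$age >= 19 & a$clinical$age <= 60))
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
  expect_error(cohort_spec(race_probs = c(black = 0.5, white = 0.2,
                                          other = 0.2)), "sum to 1")
})

test_that("declining visit shifts lower late-visit severity", {
  diffs <- vapply(1:20, function(s) {
    co <- sample_cohort(cohort_spec(n_subjects = 30, seed = s))
    mean(co$clinical$panss_p[co$clinical$visit == "day35"]) -
      mean(co$clinical$panss_p[co$clinical$visit == "screening"])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("feature targets follow the loadings and truncation", {
  spec <- cohort_spec(n_subjects = 10, seed = 7)
  # null loadings, zero noise -> targets equal intercepts
  spec0 <- spec
  spec0$loadings <- null_loadings()
  spec0$loadings$noise_sd <- 0
  t0 <- feature_targets(spec0, rep(25, 5), rep(15, 5))
  ld <- spec0$loadings
  for (f in setdiff(speech_feature_names(),
                    c("speech_length_minutes", "turn_length_minutes_mean"))) {
    expect_equal(unname(t0[, f]), rep(ld$alpha[ld$feature == f], 5),
                 info = f)
  }
  # the derived duration targets stay consistent with words and rate
  expect_equal(t0[, "speech_length_minutes"],
               t0[, "speech_length_words"] / t0[, "words_per_minute"])
  # positive loading induces positive correlation with latent severity
  set.seed(8)
  lp <- rnorm(400, 20, 4)
  tt <- feature_targets(spec, lp, rep(20, 400))
  expect_gt(cor(lp, tt[, "words_per_minute"]), 0.5)
  expect_lt(cor(lp, tt[, "word_pause_mean"]), 0)
  # default loading signs encode the expected direction structure
  ld <- default_loadings()
  amount_rate <- c("speaker_percentage", "speech_length_minutes",
                   "speech_length_words", "turn_length_minutes_mean",
                   "turn_length_words_mean", "words_per_minute",
                   "syllables_per_minute")
  pauses <- c("word_pause_mean", "word_pause_variability",
              "pre_turn_pause_mean")
  expect_true(all(ld$lambda_p[ld$feature %in% amount_rate] > 0))
  expect_true(all(ld$lambda_n[ld$feature %in% amount_rate] < 0))
  expect_true(all(ld$lambda_p[ld$feature %in% pauses] < 0))
  expect_true(all(ld$lambda_n[ld$feature %in% pauses] > 0))
})

test_that("realized transcripts reproduce their targets", {
  spec <- cohort_spec(n_subjects = 20, seed = 55)
  ds <- generate_dataset(spec)
  expect_equal(length(ds$transcripts), 100)
  ft <- extract_dataset_features(ds, identify = FALSE)
  truth <- ds$truth
  rel_err <- function(f) {
    abs(ft[[f]] - truth[[f]]) / abs(truth[[f]])
  }
  checked <- c("speech_length_minutes", "speech_length_words",
               "speaker_percentage", "turn_length_minutes_mean",
               "turn_length_words_mean", "words_per_minute",
               "syllables_per_minute", "word_pause_mean",
               "word_pause_variability", "pre_turn_pause_mean")
  for (f in checked) {
    expect_lte(median(rel_err(f)), 0.05, label = paste("median rel err", f))
  }
})

test_that("interruption probability zero yields no excluded interruptions", {
  spec <- cohort_spec(n_subjects = 4, seed = 12, interruption_prob = 0)
  ds <- generate_dataset(spec)
  ft <- extract_dataset_features(ds, identify = FALSE)
  expect_true(all(ft$n_interruptions_excluded == 0))
  # and a high probability does produce them
  spec2 <- cohort_spec(n_subjects = 4, seed = 12, interruption_prob = 0.5)
  ds2 <- generate_dataset(spec2)
  ft2 <- extract_dataset_features(ds2, identify = FALSE)
  expect_gt(sum(ft2$n_interruptions_excluded), 0)
})

test_that("generated datasets are deterministic end to end", {
  spec <- cohort_spec(n_subjects = 3, seed = 77)
  f1 <- extract_dataset_features(generate_dataset(spec))
  f2 <- extract_dataset_features(generate_dataset(spec))
  expect_identical(f1, f2)
})

test_that("blanked clinical rows are excluded from the usable count", {
  spec <- cohort_spec(n_subjects = 20, seed = 13, missing_clinical_n = 5)
  ds <- generate_dataset(spec)
  expect_equal(sum(is.na(ds$clinical$panss_p)), 5)
  ft <- extract_dataset_features(ds, identify = FALSE)
  suite <- run_association_suite(ft, ds$clinical)
  expect_equal(suite$counts$n_joined, 100)
  expect_equal(suite$counts$n_usable, 95)
  expect_equal(suite$counts$n_missing_clinical, 5)
  expect_true(all(suite$results$n_obs <= 95))
})
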