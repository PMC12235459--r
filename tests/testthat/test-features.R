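test_that("turn assembly segments at speaker changes and flags overlap", {
  tr <- m1_transcript()
  turns <- assemble_turns(tr, m1_labeling())
  expect_equal(nrow(turns), 4)
  expect_equal(turns$speaker,
               c("clinician", "participant", "clinician", "participant"))
  expect_equal(turns$word_count, c(3, 2, 3, 1))
  expect_equal(turns$span, c(0.8, 1.0, 0.9, 0.4))
  expect_false(any(turns$overlaps_previous))
  expect_equal(lengths(turns$gaps), turns$word_count - 1)

  # single speaker -> single turn
  tok <- m1_tokens()[1:3, ]
  one <- assemble_turns(new_transcript(tok, "solo", 5),
                        m1_labeling())
  expect_equal(nrow(one), 1)

  # participant starting before the clinician finishes is an overlap
  tok2 <- m1_tokens()
  tok2$start[9] <- 3.8
  tok2$end[9] <- 4.2
  turns2 <- assemble_turns(new_transcript(tok2, "ov", 5), m1_labeling())
  expect_true(turns2$overlaps_previous[4])
})

test_that("syllable heuristic matches rule traces and the oracle", {
  expect_equal(count_syllables("cat"), 1L)
  expect_equal(count_syllables("okay"), 2L)
  expect_equal(count_syllables("apple"), 2L)
  expect_equal(count_syllables(c("fine", "thanks", "interview")), c(1L, 1L, 3L))
  expect_equal(count_syllables("7"), 1L) # no letters: qc floor
  set.seed(5)
  words <- c(replicate(200, paste(sample(letters, sample(1:10, 1),
                                         replace = TRUE), collapse = "")),
             "table", "curtain", "people", "style", "rhythm")
  expect_equal(count_syllables(words),
               vapply(words, oracle_syllables, integer(1),
                      USE.NAMES = FALSE))
})

test_that("M1 features match hand computation", {
  fv <- extract_features(m1_transcript(), m1_labeling())
  exp <- m1_expected()
  for (f in names(exp)) {
    if (is.na(exp[[f]])) {
      expect_true(is.na(fv$features[[f]]), info = f)
    } else {
      expect_equal(fv$features[[f]], exp[[f]], tolerance = 1e-2, info = f)
    }
  }
  expect_equal(fv$qc$n_interruptions_excluded, 0L)
  expect_true("word_pause_variability" %in% fv$qc$missing)
})

test_that("interruptions are excluded from pre-turn pauses and counted", {
  tok <- m1_tokens()
  tok$start[9] <- 3.8 # second reply starts before the clinician ends (3.9)
  tok$end[9] <- 4.2
  fv <- extract_features(new_transcript(tok, "m1i", 5.0), m1_labeling())
  expect_equal(fv$features[["pre_turn_pause_mean"]], 0.5)
  expect_equal(fv$qc$n_interruptions_excluded, 1L)
  expect_equal(fv$qc$n_pre_turn_gaps, 1L)
})

test_that("back-to-back words give zero pause mean and variability", {
  tok <- data.frame(
    text = c("ask", "me", "one", "two", "three"),
    start = c(0, 0.3, 1.0, 1.4, 1.8),
    end = c(0.3, 0.6, 1.4, 1.8, 2.2),
    speaker_raw = c("C", "C", "P", "P", "P"), stringsAsFactors = FALSE)
  fv <- extract_features(new_transcript(tok, "b2b", 3), m1_labeling())
  expect_equal(fv$features[["word_pause_mean"]], 0)
  expect_equal(fv$features[["word_pause_variability"]], 0)
})

test_that("features are invariant to time shift and covariant to scale", {
  base <- random_stream(7)
  lab <- list(clinician_label = "A", participant_label = "B")
  f0 <- extract_features(base, lab)$features

  shifted_tokens <- base$tokens
  shifted_tokens$start <- shifted_tokens$start + 100
  shifted_tokens$end <- shifted_tokens$end + 100
  shifted <- new_transcript(shifted_tokens, "s",
                            file_duration = base$file_duration)
  # same file duration: speaker percentage unchanged too
  f1 <- extract_features(shifted, lab)$features
  expect_equal(f1, f0, tolerance = 1e-9)

  k <- 2.5
  scaled_tokens <- base$tokens
  scaled_tokens$start <- scaled_tokens$start * k
  scaled_tokens$end <- scaled_tokens$end * k
  scaled <- new_transcript(scaled_tokens, "k",
                           file_duration = base$file_duration * k)
  f2 <- extract_features(scaled, lab)$features
  time_feats <- c("speech_length_minutes", "turn_length_minutes_mean",
                  "word_pause_mean", "word_pause_variability",
                  "pre_turn_pause_mean")
  rate_feats <- c("words_per_minute", "syllables_per_minute")
  fixed <- setdiff(names(f0), c(time_feats, rate_feats))
  expect_equal(f2[time_feats], f0[time_feats] * k, tolerance = 1e-9)
  expect_equal(f2[rate_feats], f0[rate_feats] / k, tolerance = 1e-9)
  expect_equal(f2[fixed], f0[fixed], tolerance = 1e-9)
})

test_that("clinician + participant speaker percentages stay within 100", {
  for (seed in 1:25) {
    tr <- random_stream(seed)
    turns <- assemble_turns(tr, list(clinician_label = "A",
                                     participant_label = "B"))
    if (any(turns$overlaps_previous)) next
    spans <- tapply(turns$span, turns$speaker, sum)
    expect_lte(sum(spans) / tr$file_duration * 100, 100 + 1e-9)
  }
})

test_that("per-turn rate definition differs from pooled on uneven turns", {
  tr <- m1_transcript()
  pooled <- extract_features(tr, m1_labeling(),
                             rate_definition = "pooled")$features
  per_turn <- extract_features(tr, m1_labeling(),
                               rate_definition = "per_turn")$features
  # M1: pooled 3/(1.4/60); per-turn mean of 2/(1/60) and 1/(0.4/60)
  expect_equal(pooled[["words_per_minute"]], 128.5714, tolerance = 1e-3)
  expect_equal(per_turn[["words_per_minute"]], mean(c(120, 150)),
               tolerance = 1e-9)
})

test_that("zero participant turns is an error", {
  tok <- m1_tokens()[c(1:3, 6:8), ] # clinician only
  tr <- new_transcript(tok, "c_only", 5)
  expect_error(
    extract_features(tr, list(clinician_label = "C",
                              participant_label = "P")),
    "participant has no turns")
})
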