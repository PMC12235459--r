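# Seeded synthetic cohort generator: mock two-speaker structured
# interviews whose word timings realize target values of the twelve
# speech characteristics, linked to latent severity by linear loadings.
# It lets every stage of the pipeline be exercised without access to
# protected recordings.

#' Default feature loadings linking latent severity to feature targets
#'
#' One row per feature: intercept `alpha` (the cohort-mean feature
#' value), loadings `lambda_p`/`lambda_n` on centered latent positive and
#' negative severity, target noise `noise_sd`, and the truncation range.
#' The sign pattern follows the expected clinical direction structure:
#' amount and rate of speech load positively on positive severity and
#' negatively on negative severity; pause features the reverse; positive
#' sentiment loads negatively on positive severity; negative sentiment
#' loads positively on both.
#'
#' The two duration features that are arithmetically tied to others
#' (speech length in minutes = words / WPM; mean turn length in minutes
#' ~ turn words / WPM) carry loadings consistent with that implied
#' relation, so their realized values agree with their targets.
#'
#' @return data.frame with columns `feature`, `alpha`, `lambda_p`,
#'   `lambda_n`, `noise_sd`, `min`, `max`.
#' @export
default_loadings <- function() {
  df <- rbind(
    data.frame(feature = "speech_length_minutes", alpha = 240 / 140,
               lambda_p = 0.0173, lambda_n = -0.0102, noise_sd = 0.03,
               min = 0.2, max = 20),
    data.frame(feature = "speech_length_words", alpha = 240,
               lambda_p = 5, lambda_n = -4, noise_sd = 12,
               min = 30, max = 2000),
    data.frame(feature = "speaker_percentage", alpha = 30,
               lambda_p = 0.4, lambda_n = -0.4, noise_sd = 3,
               min = 2, max = 90),
    data.frame(feature = "turn_length_minutes_mean", alpha = 12 / 140,
               lambda_p = 0.00158, lambda_n = -0.00158, noise_sd = 0.002,
               min = 0.01, max = 2),
    data.frame(feature = "turn_length_words_mean", alpha = 12,
               lambda_p = 0.35, lambda_n = -0.35, noise_sd = 0.8,
               min = 2, max = 80),
    data.frame(feature = "words_per_minute", alpha = 140,
               lambda_p = 1.5, lambda_n = -1.5, noise_sd = 7,
               min = 60, max = 240),
    data.frame(feature = "syllables_per_minute", alpha = 195,
               lambda_p = 2.2, lambda_n = -2.2, noise_sd = 9,
               min = 70, max = 460),
    data.frame(feature = "word_pause_mean", alpha = 0.25,
               lambda_p = -0.004, lambda_n = 0.006, noise_sd = 0.018,
               min = 0.02, max = 1.5),
    data.frame(feature = "word_pause_variability", alpha = 0.18,
               lambda_p = -0.002, lambda_n = 0.004, noise_sd = 0.012,
               min = 0.02, max = 1.2),
    data.frame(feature = "pre_turn_pause_mean", alpha = 1.2,
               lambda_p = -0.03, lambda_n = 0.05, noise_sd = 0.1,
               min = 0.1, max = 6),
    data.frame(feature = "sentiment_positive", alpha = 0.08,
               lambda_p = -0.004, lambda_n = 0, noise_sd = 0.008,
               min = 0.005, max = 0.4),
    data.frame(feature = "sentiment_negative", alpha = 0.05,
               lambda_p = 0.003, lambda_n = 0.003, noise_sd = 0.006,
               min = 0.005, max = 0.4)
  )
  rownames(df) <- NULL
  df
}

#' Null loadings (all severity-feature links zero)
#'
#' Same intercepts and noise as [default_loadings()] but every loading
#' set to zero; used for null-calibration runs.
#' @return data.frame as in [default_loadings()].
#' @export
null_loadings <- function() {
  df <- default_loadings()
  df$lambda_p <- 0
  df$lambda_n <- 0
  df
}

#' Generative specification for a synthetic cohort
#'
#' Defaults emulate a 5-visit schizophrenia trial cohort: 150 subjects,
#' ages 19-60 (mean ~43), ~23% female, ~76% black; latent positive and
#' negative severity with per-subject random intercepts (sd 4 score
#' points), per-visit shifts declining over the study (a treatment-like
#' trajectory), and visit-level noise; PANSS subscale scores are the
#' rounded latents clipped to [7, 49]. Feature targets follow the linear
#' loadings; interviews are compact mock structured interviews
#' (participant ~240 words over ~20 turns in a ~6 minute file).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param visits ordered visit labels.
#' @param seed integer seed; every random draw in the generator flows
#'   from it.
#' @param prop_female,race_probs demographic model.
#' @param age_mean,age_sd,age_range truncated-normal age model.
#' @param severity list: `p_mean`, `p_subject_sd`, `p_visit_shift`,
#'   `p_resid_sd` and the `n_*` counterparts.
#' @param loadings data.frame as [default_loadings()].
#' @param interruption_prob probability a participant turn starts before
#'   the clinician finishes (negative pre-turn gap).
#' @param prompt_dropout per-word deletion probability applied to
#'   clinician prompts (simulates transcription loss).
#' @param missing_clinical_n number of clinical rows whose PANSS scores
#'   are blanked (emulates interviews without clinical data).
#' @param prompts clinician prompt texts.
#' @param clinician_wpm clinician speaking rate (words/minute).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 150,
                        visits = visit_levels(),
                        seed = 1,
                        prop_female = 0.234,
                        race_probs = c(black = 0.756, white = 0.21,
                                       other = 0.034),
                        age_mean = 43, age_sd = 10, age_range = c(19, 60),
                        severity = list(
                          p_mean = 20, p_subject_sd = 4,
                          p_visit_shift = c(0, -0.5, -2, -3.5, -4.5),
                          p_resid_sd = 1.5,
                          n_mean = 20, n_subject_sd = 4,
                          n_visit_shift = c(0, -0.5, -1.5, -3, -4),
                          n_resid_sd = 1.5),
                        loadings = default_loadings(),
                        interruption_prob = 0.05,
                        prompt_dropout = 0,
                        missing_clinical_n = 0,
                        prompts = default_prompts(),
                        clinician_wpm = 160) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (anyDuplicated(visits)) stop("visit labels must be unique")
  if (abs(sum(race_probs) - 1) > 1e-8) {
    stop("race_probs must sum to 1")
  }
  if (prop_female < 0 || prop_female > 1) stop("prop_female must be in [0,1]")
  stopifnot(is.data.frame(loadings))
  missing_feats <- setdiff(speech_feature_names(), loadings$feature)
  if (length(missing_feats) > 0) {
    stop("loadings must cover all 12 features; missing: ",
         paste(missing_feats, collapse = ", "))
  }
  if (any(loadings$noise_sd < 0)) stop("noise sds must be >= 0")
  if (length(severity$p_visit_shift) != length(visits) ||
      length(severity$n_visit_shift) != length(visits)) {
    stop("visit shift vectors must match the number of visits")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), visits = visits,
    seed = as.integer(seed), prop_female = prop_female,
    race_probs = race_probs, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, severity = severity, loadings = loadings,
    interruption_prob = interruption_prob, prompt_dropout = prompt_dropout,
    missing_clinical_n = as.integer(missing_clinical_n),
    prompts = prompts, clinician_wpm = clinician_wpm
  ), class = "cohort_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Draw the clinical table and latent severity matrix
#'
#' Seeded and reproducible: the same spec yields identical output on
#' every call. Integer PANSS subscale scores are the rounded latent
#' values clipped into [7, 49]; clip events are counted.
#'
#' @param spec a [cohort_spec()].
#' @return list: `clinical` (one row per subject x visit), `latent`
#'   (matching rows of `latent_p`, `latent_n`), `clip_events`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    subject_id <- sprintf("S%03d", seq_len(n))
    age <- round(pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                           spec$age_range[1]), spec$age_range[2]))
    sex <- ifelse(stats::runif(n) < spec$prop_female, "female", "male")
    race <- sample(names(spec$race_probs), n, replace = TRUE,
                   prob = spec$race_probs)
    sv <- spec$severity
    p_int <- stats::rnorm(n, sv$p_mean, sv$p_subject_sd)
    n_int <- stats::rnorm(n, sv$n_mean, sv$n_subject_sd)
    nv <- length(spec$visits)
    rows <- expand.grid(visit_idx = seq_len(nv), subj = seq_len(n))
    latent_p <- p_int[rows$subj] + sv$p_visit_shift[rows$visit_idx] +
      stats::rnorm(nrow(rows), 0, sv$p_resid_sd)
    latent_n <- n_int[rows$subj] + sv$n_visit_shift[rows$visit_idx] +
      stats::rnorm(nrow(rows), 0, sv$n_resid_sd)
    score_p <- round(pmin(pmax(latent_p, 7), 49))
    score_n <- round(pmin(pmax(latent_n, 7), 49))
    clip_events <- sum(latent_p < 7 | latent_p > 49) +
      sum(latent_n < 7 | latent_n > 49)
    clinical <- data.frame(
      subject_id = subject_id[rows$subj],
      visit = spec$visits[rows$visit_idx],
      age = age[rows$subj],
      sex = sex[rows$subj],
      race = race[rows$subj],
      panss_p = as.integer(score_p),
      panss_n = as.integer(score_n),
      stringsAsFactors = FALSE
    )
    latent <- data.frame(
      subject_id = clinical$subject_id, visit = clinical$visit,
      latent_p = latent_p, latent_n = latent_n,
      stringsAsFactors = FALSE
    )
    list(clinical = clinical, latent = latent, clip_events = clip_events)
  })
}

#' Feature targets from latent severity
#'
#' `target_j = alpha_j + lambda_{j,P} (P - P0) + lambda_{j,N} (N - N0) +
#' noise_j`, truncated to each feature's valid range (`P0`/`N0` are the
#' severity model means, so `alpha` is the cohort-mean feature value).
#' Draws use the current RNG state; seed externally for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @param latent_p,latent_n numeric vectors of latent severity.
#' @return matrix (rows = interviews, columns = the 12 features), with a
#'   `truncated` attribute counting truncation events.
#' @export
feature_targets <- function(spec, latent_p, latent_n) {
  stopifnot(length(latent_p) == length(latent_n))
  ld <- spec$loadings[match(speech_feature_names(), spec$loadings$feature), ]
  dp <- latent_p - spec$severity$p_mean
  dn <- latent_n - spec$severity$n_mean
  n <- length(latent_p)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(ld),
                dimnames = list(NULL, ld$feature))
  truncated <- 0L
  for (j in seq_len(nrow(ld))) {
    t_j <- ld$alpha[j] + ld$lambda_p[j] * dp + ld$lambda_n[j] * dn +
      stats::rnorm(n, 0, ld$noise_sd[j])
    clipped <- pmin(pmax(t_j, ld$min[j]), ld$max[j])
    truncated <- truncated + sum(clipped != t_j)
    out[, j] <- clipped
  }
  # the two derived duration targets are harmonized to the driver targets
  # (words and rate), so realized transcripts reproduce them faithfully
  out[, "speech_length_minutes"] <-
    out[, "speech_length_words"] / out[, "words_per_minute"]
  out[, "turn_length_minutes_mean"] <-
    out[, "speech_length_minutes"] * out[, "turn_length_words_mean"] /
    out[, "speech_length_words"]
  attr(out, "truncated") <- truncated
  out
}

# moment-matched log-normal draws with target mean m and sd s
rlnorm_ms <- function(n, m, s) {
  if (n == 0) return(numeric(0))
  sdlog2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# word pools partitioned by syllable count, computed once per session
generator_pools <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      neutral <- unique(readLines(
        system.file("extdata", "neutral_words.txt",
                    package = "speechmarkers"), warn = FALSE))
      neutral <- neutral[nzchar(neutral)]
      syl <- count_syllables(neutral)
      pos <- unique(readLines(
        system.file("extdata", "sentiment_positive.txt",
                    package = "speechmarkers"), warn = FALSE))
      neg <- unique(readLines(
        system.file("extdata", "sentiment_negative.txt",
                    package = "speechmarkers"), warn = FALSE))
      pos <- pos[nzchar(pos)]
      neg <- neg[nzchar(neg)]
      cache <<- list(
        neutral1 = neutral[syl == 1],
        neutral2 = neutral[syl >= 2],
        pos = pos, neg = neg,
        pos_syl = mean(count_syllables(pos)),
        neg_syl = mean(count_syllables(neg))
      )
    }
    cache
  }
})

#' Realize one mock interview transcript from feature targets
#'
#' Builds an alternating clinician-prompt / participant-response
#' transcript whose word timings realize the target features:
#' participant word count, turn structure, per-word durations (scaled by
#' syllable count to hit the words/syllables-per-minute targets),
#' intra-turn gaps (log-normal, moment-matched to the target pause mean
#' and sd) and pre-turn gaps. Sentiment-bearing words are mixed in at
#' rates matching the sentiment targets. With probability
#' `spec$interruption_prob` a participant turn starts before the
#' clinician's turn ends (a negative pre-turn gap, kept small enough not
#' to reorder tokens). The file duration is set so the target speaker
#' percentage holds exactly.
#'
#' @param targets named numeric vector of the 12 feature targets.
#' @param prompts clinician prompt texts.
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this interview.
#' @param interview_id identifier.
#' @return A [new_transcript()] object; attribute `clinician_label`
#'   records the ground-truth raw label of the clinician.
#' @export
realize_transcript <- function(targets, prompts, spec, seed,
                               interview_id = "interview") {
  with_seed(seed, {
    pools <- generator_pools()
    W <- max(2L, as.integer(round(targets[["speech_length_words"]])))
    wbar <- max(1, targets[["turn_length_words_mean"]])
    n_turns <- max(1L, as.integer(round(W / wbar)))
    # words per turn: at least one word each
    extra <- W - n_turns
    counts <- if (extra > 0) {
      as.vector(stats::rmultinom(1, extra, rep(1, n_turns))) + 1L
    } else rep(1L, n_turns)

    wpm <- targets[["words_per_minute"]]
    spm <- targets[["syllables_per_minute"]]
    S <- W / wpm * 60 # total participant speaking time, seconds
    n_gaps <- W - n_turns
    gaps <- rlnorm_ms(n_gaps, targets[["word_pause_mean"]],
                      targets[["word_pause_variability"]])
    # moment-match the realized sample to the targets (clamp floor, then
    # re-center the mean), so extracted pause statistics hit the targets
    if (n_gaps >= 2 && stats::sd(gaps) > 0) {
      gaps <- targets[["word_pause_mean"]] +
        (gaps - mean(gaps)) * targets[["word_pause_variability"]] /
        stats::sd(gaps)
      gaps <- pmax(gaps, 0.02)
      gaps <- gaps + (targets[["word_pause_mean"]] - mean(gaps))
      gaps <- pmax(gaps, 0.01)
    }
    word_time <- S - sum(gaps)
    if (word_time < 0.03 * W) {
      stop(sprintf(
        "infeasible targets for '%s': pauses (%.1f s) leave %.2f s for %d words",
        interview_id, sum(gaps), word_time, W))
    }

    # choose participant words: sentiment mixing + syllable-ratio matching
    p_pos <- targets[["sentiment_positive"]]
    p_neg <- targets[["sentiment_negative"]]
    r_target <- min(max(spm / wpm, 1.02), 1.98)
    f_sent <- p_pos + p_neg
    r_sent <- if (f_sent > 0) {
      (p_pos * pools$pos_syl + p_neg * pools$neg_syl) / f_sent
    } else 1
    q2 <- (r_target - f_sent * r_sent - (1 - f_sent)) / (1 - f_sent)
    q2 <- min(max(q2, 0), 1)
    u <- stats::runif(W)
    kind <- ifelse(u < p_pos, "pos",
                   ifelse(u < p_pos + p_neg, "neg",
                          ifelse(stats::runif(W) < q2, "n2", "n1")))
    words <- character(W)
    for (k in c("pos", "neg", "n1", "n2")) {
      idx <- which(kind == k)
      if (length(idx) == 0) next
      pool <- switch(k, pos = pools$pos, neg = pools$neg,
                     n1 = pools$neutral1, n2 = pools$neutral2)
      words[idx] <- sample(pool, length(idx), replace = TRUE)
    }
    syll <- count_syllables(words)
    durations <- word_time * syll / sum(syll)

    # clinician turns: prompts with optional word dropout
    prompt_idx <- if (length(prompts) >= n_turns) {
      sample(seq_along(prompts), n_turns)
    } else {
      sample(rep(seq_along(prompts),
                 ceiling(n_turns / length(prompts)))[seq_len(n_turns)])
    }
    clin_words <- lapply(prompt_idx, function(i) {
      w <- strsplit(prompts[i], "\\s+")[[1]]
      if (spec$prompt_dropout > 0) {
        keep <- stats::runif(length(w)) >= spec$prompt_dropout
        if (!any(keep)) keep[sample(length(w), 1)] <- TRUE
        w <- w[keep]
      }
      w
    })
    clin_dur <- 60 / spec$clinician_wpm
    clin_gap <- 0.05
    clin_span <- vapply(clin_words, function(w) {
      length(w) * clin_dur + (length(w) - 1) * clin_gap
    }, numeric(1))

    pre_mean <- targets[["pre_turn_pause_mean"]]
    pre_gaps <- rlnorm_ms(n_turns, pre_mean, 0.25 * pre_mean)
    interrupt <- stats::runif(n_turns) < spec$interruption_prob
    # an interruption overlaps only the clinician's final word, so token
    # start order still matches turn order
    pre_gaps[interrupt] <- -stats::runif(sum(interrupt), 0.3, 0.8) * clin_dur
    if (any(!interrupt)) {
      # re-center retained gaps so the extracted pre-turn pause mean
      # (which excludes interruptions) matches the target
      keep <- which(!interrupt)
      pre_gaps[keep] <- pmax(0.05, pre_gaps[keep] *
                               pre_mean / mean(pre_gaps[keep]))
    }

    p_span_total <- S
    pct <- targets[["speaker_percentage"]]
    file_duration <- p_span_total / (pct / 100)
    tail_s <- 2
    leftover <- file_duration - sum(clin_span) - sum(pre_gaps) -
      p_span_total - tail_s
    if (leftover < 0.1 * n_turns) {
      # compress clinician delivery before giving up
      clin_dur <- max(0.12, clin_dur * 0.6)
      clin_gap <- 0.02
      clin_span <- vapply(clin_words, function(w) {
        length(w) * clin_dur + (length(w) - 1) * clin_gap
      }, numeric(1))
      leftover <- file_duration - sum(clin_span) - sum(pre_gaps) -
        p_span_total - tail_s
      if (leftover < 0) {
        stop(sprintf(
          "infeasible targets for '%s': speaker percentage %.1f%% leaves no room for the clinician",
          interview_id, pct))
      }
    }
    jitter <- stats::runif(n_turns, 0.5, 1.5)
    post_gaps <- leftover * jitter / sum(jitter)

    # assign raw labels at random so identification is non-trivial
    clin_label <- sample(c("spk_0", "spk_1"), 1)
    part_label <- setdiff(c("spk_0", "spk_1"), clin_label)

    gap_split <- rep(list(numeric(0)), n_turns)
    if (n_gaps > 0) {
      gl <- split(gaps, rep.int(seq_len(n_turns), counts - 1L))
      gap_split[as.integer(names(gl))] <- gl
    }
    n_clin <- vapply(clin_words, length, integer(1))
    total_tokens <- sum(n_clin) + W
    tok_text <- character(total_tokens)
    tok_start <- numeric(total_tokens)
    tok_end <- numeric(total_tokens)
    tok_speaker <- character(total_tokens)
    t_now <- 1.0
    wi <- 1L
    ti <- 1L
    for (i in seq_len(n_turns)) {
      nc <- n_clin[i]
      c_starts <- t_now + (seq_len(nc) - 1) * (clin_dur + clin_gap)
      c_ends <- c_starts + clin_dur
      cidx <- ti:(ti + nc - 1L)
      tok_text[cidx] <- clin_words[[i]]
      tok_start[cidx] <- c_starts
      tok_end[cidx] <- c_ends
      tok_speaker[cidx] <- clin_label
      ti <- ti + nc
      p_start <- c_ends[nc] + pre_gaps[i]
      nw <- counts[i]
      idx <- wi:(wi + nw - 1L)
      d_i <- durations[idx]
      starts_i <- p_start + c(0, cumsum(d_i[-nw] + gap_split[[i]]))
      pidx <- ti:(ti + nw - 1L)
      tok_text[pidx] <- words[idx]
      tok_start[pidx] <- starts_i
      tok_end[pidx] <- starts_i + d_i
      tok_speaker[pidx] <- part_label
      ti <- ti + nw
      wi <- wi + nw
      t_now <- tok_end[pidx[nw]] + post_gaps[i]
    }
    tokens <- data.frame(text = tok_text, start = tok_start, end = tok_end,
                         speaker_raw = tok_speaker, stringsAsFactors = FALSE)
    tr <- new_transcript(tokens, interview_id = interview_id,
                         file_duration = file_duration)
    attr(tr, "clinician_label") <- clin_label
    tr
  })
}

#' Generate a complete synthetic dataset
#'
#' Composes [sample_cohort()], [feature_targets()] and
#' [realize_transcript()]: one transcript per (subject, visit) clinical
#' row, with the ground-truth targets and clinician labels recorded next
#' to the data. Optionally writes everything to disk (word_records
#' transcripts under `dir/transcripts/<visit>/`, `clinical.csv`,
#' `truth.json`).
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @return list of class `synthetic_dataset`: `transcripts` (named list),
#'   `clinical`, `truth` (data.frame of per-interview targets, latents
#'   and clinician labels), `clip_events`, `spec`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  cohort <- sample_cohort(spec)
  clinical <- cohort$clinical
  n <- nrow(clinical)
  targets <- with_seed((spec$seed + 104729L) %% .Machine$integer.max, {
    feature_targets(spec, cohort$latent$latent_p, cohort$latent$latent_n)
  })
  interview_id <- paste(clinical$subject_id, clinical$visit, sep = "_")
  transcripts <- vector("list", n)
  clin_labels <- character(n)
  for (i in seq_len(n)) {
    seed_i <- (spec$seed * 7L + i * 13L) %% .Machine$integer.max
    tr <- realize_transcript(targets[i, ], spec$prompts, spec, seed_i,
                             interview_id = interview_id[i])
    transcripts[[i]] <- tr
    clin_labels[i] <- attr(tr, "clinician_label")
  }
  names(transcripts) <- interview_id
  if (spec$missing_clinical_n > 0) {
    blank <- with_seed((spec$seed + 15485863L) %% .Machine$integer.max, {
      sample(n, min(spec$missing_clinical_n, n))
    })
    clinical$panss_p[blank] <- NA_integer_
    clinical$panss_n[blank] <- NA_integer_
  }
  truth <- cbind(
    data.frame(interview_id = interview_id,
               subject_id = clinical$subject_id, visit = clinical$visit,
               clinician_label = clin_labels,
               latent_p = cohort$latent$latent_p,
               latent_n = cohort$latent$latent_n,
               stringsAsFactors = FALSE),
    as.data.frame(targets)
  )
  ds <- structure(list(
    transcripts = transcripts, clinical = clinical, truth = truth,
    clip_events = cohort$clip_events, spec = spec
  ), class = "synthetic_dataset")
  if (!is.null(dir)) {
    write_dataset(ds, dir)
  }
  ds
}

#' Write a synthetic dataset to disk
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(dir, "transcripts")
  for (v in unique(ds$clinical$visit)) {
    dir.create(file.path(tdir, v), recursive = TRUE, showWarnings = FALSE)
  }
  for (id in names(ds$transcripts)) {
    v <- ds$transcripts[[id]]
    visit <- ds$clinical$visit[match(id, paste(ds$clinical$subject_id,
                                               ds$clinical$visit, sep = "_"))]
    write_transcript(v, file.path(tdir, visit, paste0(id, ".jsonl")))
  }
  clin <- ds$clinical
  utils::write.csv(clin, file.path(dir, "clinical.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d interviews (%d subjects x %d visits), seed %d>\n",
    length(x$transcripts), x$spec$n_subjects, length(x$spec$visits),
    x$spec$seed))
  invisible(x)
}
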