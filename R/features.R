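# Turn assembly and the twelve speech characteristics.
#
# All internal computation is in seconds; minutes appear only in the
# emitted feature values. A turn is a maximal run of consecutive tokens
# (sorted by start time) sharing one speaker; turn boundaries occur
# exactly at speaker changes.

#' Assemble clinician/participant turns from a labeled transcript
#'
#' @param transcript a [new_transcript()] object.
#' @param labeling a `speaker_labeling` from [identify_participant()], or
#'   a named list with `clinician_label` and `participant_label`.
#' @return data.frame of class `turns`, one row per turn in time order:
#'   `speaker` ("clinician"/"participant"), `start`, `end`, `span`,
#'   `word_count`, `overlaps_previous`, plus list-columns `gaps`
#'   (intra-turn between-word gaps, clamped at 0), `words_clean` and a
#'   `text` column (the turn's raw text).
#' @export
assemble_turns <- function(transcript, labeling) {
  stopifnot(inherits(transcript, "transcript"))
  tk <- transcript$tokens
  role <- ifelse(tk$speaker_raw == labeling$clinician_label, "clinician",
                 ifelse(tk$speaker_raw == labeling$participant_label,
                        "participant", NA_character_))
  if (anyNA(role)) {
    bad <- unique(tk$speaker_raw[is.na(role)])
    stop("speaker label(s) not covered by the labeling: ",
         paste(bad, collapse = ", "))
  }
  runs <- rle(role)
  stops <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(stops, -1) + 1L)
  n <- length(runs$values)
  start <- tk$start[starts_idx]
  end <- tk$end[stops]
  turn_id <- rep.int(seq_len(n), runs$lengths)
  nt <- nrow(tk)
  gaps <- rep(list(numeric(0)), n)
  if (nt > 1) {
    same <- turn_id[-1] == turn_id[-nt]
    # negative intra-turn gaps are timing jitter; clamp at 0
    g <- pmax(tk$start[-1][same] - tk$end[-nt][same], 0)
    gl <- split(g, turn_id[-1][same])
    gaps[as.integer(names(gl))] <- gl
  }
  words_clean <- split(tk$text_clean, turn_id)
  names(words_clean) <- NULL
  text <- vapply(split(tk$text, turn_id), paste, character(1),
                 collapse = " ", USE.NAMES = FALSE)
  out <- data.frame(
    speaker = runs$values,
    start = start,
    end = end,
    span = end - start,
    word_count = runs$lengths,
    overlaps_previous = c(FALSE, start[-1] < end[-n]),
    stringsAsFactors = FALSE
  )
  out$gaps <- gaps
  out$words_clean <- words_clean
  out$text <- text
  class(out) <- c("turns", "data.frame")
  out
}

#' Heuristic syllable count for one word
#'
#' Counts maximal contiguous vowel groups (a, e, i, o, u, y,
#' case-insensitive); a final silent "e" (not "le") is discounted when
#' more than one group is present; floor at 1. A token with no letters
#' counts as 1 syllable.
#'
#' @param word character vector of words.
#' @return Integer vector of counts (each >= 1).
#' @export
count_syllables <- function(word) {
  u <- unique(word)
  w <- tolower(gsub("[^a-zA-Z]", "", u))
  k <- vapply(gregexpr("[aeiouy]+", w),
              function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  silent_e <- k > 1L & grepl("e$", w) & !grepl("le$", w)
  k[silent_e] <- k[silent_e] - 1L
  pmax(k, 1L)[match(word, u)]
}

#' Bundled lexicon-based sentiment scorer
#'
#' Returns a scorer implementing the sentiment contract: a function that
#' maps a character vector of (cleaned) words to a named numeric vector
#' `c(positive =, negative =)` giving the fraction of words matching the
#' bundled positive/negative valence lexicons. A model-based valence
#' scorer with the same contract can be substituted.
#'
#' @return A scorer function.
#' @export
lexicon_sentiment <- function() {
  pos <- unique(readLines(system.file("extdata", "sentiment_positive.txt",
                                      package = "speechmarkers"),
                          warn = FALSE))
  neg <- unique(readLines(system.file("extdata", "sentiment_negative.txt",
                                      package = "speechmarkers"),
                          warn = FALSE))
  pos <- pos[nzchar(pos)]
  neg <- neg[nzchar(neg)]
  function(words) {
    words <- words[nzchar(words)]
    if (length(words) == 0) {
      return(c(positive = NA_real_, negative = NA_real_))
    }
    c(positive = mean(words %in% pos), negative = mean(words %in% neg))
  }
}

#' Extract the twelve speech characteristics for the participant
#'
#' Computes, over the participant's turns: amount of speech (speech
#' length in minutes and words, speaker percentage of the file, mean turn
#' length in minutes and words), rate of speech (words and syllables per
#' minute), pause characteristics (mean and standard deviation of
#' between-word pauses, mean pre-turn pause), and lexicon-based positive
#' and negative sentiment. Speaking time is turn span (last word end
#' minus first word start), so short intra-turn pauses count as speaking
#' time. Pre-turn pauses are measured only where the immediately
#' preceding turn is the clinician's; a negative gap is an interruption
#' and is excluded from the average (counted in
#' `qc$n_interruptions_excluded`). Features with insufficient support
#' (e.g. the pause standard deviation with fewer than two gaps) are
#' emitted as `NA`, never fabricated as 0.
#'
#' @param transcript a [new_transcript()] object.
#' @param labeling a `speaker_labeling` (see [identify_participant()]).
#' @param sentiment sentiment scorer contract; see [lexicon_sentiment()].
#' @param rate_definition `"pooled"` (total words over total speaking
#'   time; the default) or `"per_turn"` (unweighted mean of per-turn
#'   rates) for the two rate features.
#' @return An object of class `feature_vector`: a list with `features`
#'   (named numeric of length 12), `qc` (support counts and missing
#'   markers) and `interview_id`.
#' @export
extract_features <- function(transcript, labeling,
                             sentiment = lexicon_sentiment(),
                             rate_definition = c("pooled", "per_turn")) {
  rate_definition <- match.arg(rate_definition)
  turns <- assemble_turns(transcript, labeling)
  p <- turns[turns$speaker == "participant", , drop = FALSE]
  if (nrow(p) == 0) {
    stop("participant has no turns in transcript '",
         transcript$interview_id, "'")
  }
  file_duration <- transcript$file_duration
  total_span <- sum(p$span)
  total_words <- sum(p$word_count)
  total_syll <- sum(vapply(p$words_clean,
                           function(w) sum(count_syllables(w)), numeric(1)))

  word_gaps <- unlist(p$gaps)
  n_word_gaps <- length(word_gaps)

  # pre-turn pauses: participant turns whose immediate predecessor is a
  # clinician turn; negative gaps are interruptions and are excluded
  p_rows <- which(turns$speaker == "participant")
  pre_gaps <- numeric(0)
  n_interruptions <- 0L
  for (i in p_rows) {
    if (i > 1 && turns$speaker[i - 1] == "clinician") {
      g <- turns$start[i] - turns$end[i - 1]
      if (g < 0) {
        n_interruptions <- n_interruptions + 1L
      } else {
        pre_gaps <- c(pre_gaps, g)
      }
    }
  }

  rate <- function(pooled_num, per_turn_num) {
    if (rate_definition == "pooled") {
      if (total_span > 0) pooled_num / (total_span / 60) else NA_real_
    } else {
      ok <- p$span > 0
      if (any(ok)) mean(per_turn_num[ok] / (p$span[ok] / 60)) else NA_real_
    }
  }
  per_turn_syll <- vapply(p$words_clean,
                          function(w) sum(count_syllables(w)), numeric(1))

  sent <- t(vapply(p$words_clean, sentiment, numeric(2)))
  w <- p$word_count / sum(p$word_count)
  sent_pos <- sum(w * sent[, 1])
  sent_neg <- sum(w * sent[, 2])

  feats <- c(
    speech_length_minutes = total_span / 60,
    speech_length_words = as.numeric(total_words),
    speaker_percentage = 100 * total_span / file_duration,
    turn_length_minutes_mean = mean(p$span) / 60,
    turn_length_words_mean = mean(p$word_count),
    words_per_minute = rate(total_words, p$word_count),
    syllables_per_minute = rate(total_syll, per_turn_syll),
    word_pause_mean = if (n_word_gaps >= 1) mean(word_gaps) else NA_real_,
    word_pause_variability = if (n_word_gaps >= 2) stats::sd(word_gaps)
                             else NA_real_,
    pre_turn_pause_mean = if (length(pre_gaps) >= 1) mean(pre_gaps)
                          else NA_real_,
    sentiment_positive = sent_pos,
    sentiment_negative = sent_neg
  )
  qc <- list(
    n_turns = nrow(p),
    n_word_gaps = n_word_gaps,
    n_pre_turn_gaps = length(pre_gaps),
    n_interruptions_excluded = n_interruptions,
    file_duration = file_duration,
    file_duration_derived = transcript$duration_derived,
    missing = names(feats)[is.na(feats)]
  )
  structure(
    list(features = feats, qc = qc, interview_id = transcript$interview_id),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector '%s' (%d participant turns)>\n",
              x$interview_id, x$qc$n_turns))
  print(round(x$features, 4))
  invisible(x)
}

#' One-row data.frame from a feature vector
#'
#' @param fv a `feature_vector` from [extract_features()].
#' @return data.frame with `interview_id`, the 12 feature columns,
#'   `file_duration` and qc counts.
#' @export
as_feature_row <- function(fv) {
  stopifnot(inherits(fv, "feature_vector"))
  row <- as.data.frame(as.list(fv$features))
  cbind(
    data.frame(interview_id = fv$interview_id, stringsAsFactors = FALSE),
    row,
    data.frame(
      file_duration = fv$qc$file_duration,
      n_turns = fv$qc$n_turns,
      n_word_gaps = fv$qc$n_word_gaps,
      n_pre_turn_gaps = fv$qc$n_pre_turn_gaps,
      n_interruptions_excluded = fv$qc$n_interruptions_excluded
    )
  )
}
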