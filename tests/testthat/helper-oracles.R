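# Shared fixtures and independent brute-force oracles. The oracles
# deliberately re-derive everything with plain loops so they share no
# code path with the package implementation they check.

# -- M1 micro-transcript: two clinician prompts, two participant replies.
# C: "how are you" 0.0-0.8 | P: "fine thanks" 1.3-2.3 |
# C: "tell me more" 3.0-3.9 | P: "okay" 4.4-4.8; file 5.0 s.
m1_tokens <- function() {
  data.frame(
    text = c("how", "are", "you", "fine", "thanks",
             "tell", "me", "more", "okay"),
    start = c(0.0, 0.3, 0.6, 1.3, 1.9, 3.0, 3.3, 3.6, 4.4),
    end   = c(0.2, 0.5, 0.8, 1.7, 2.3, 3.2, 3.5, 3.9, 4.8),
    speaker_raw = c("C", "C", "C", "P", "P", "C", "C", "C", "P"),
    stringsAsFactors = FALSE
  )
}

m1_transcript <- function() {
  new_transcript(m1_tokens(), interview_id = "m1", file_duration = 5.0)
}

m1_labeling <- function() {
  list(clinician_label = "C", participant_label = "P")
}

# hand-computed expectations for M1 (participant spans 1.0 s + 0.4 s)
m1_expected <- function() {
  c(speech_length_minutes = 1.4 / 60,
    speech_length_words = 3,
    speaker_percentage = 28.0,
    turn_length_minutes_mean = 0.7 / 60,
    turn_length_words_mean = 1.5,
    words_per_minute = 3 / (1.4 / 60),
    syllables_per_minute = 4 / (1.4 / 60),
    word_pause_mean = 0.2,
    word_pause_variability = NA_real_,
    pre_turn_pause_mean = 0.5)
}

# -- independent syllable counter: explicit character loop
oracle_syllables <- function(word) {
  w <- tolower(word)
  w <- paste(Filter(function(ch) ch %in% letters,
                    strsplit(w, "")[[1]]), collapse = "")
  if (!nzchar(w)) return(1L)
  chars <- strsplit(w, "")[[1]]
  vowels <- c("a", "e", "i", "o", "u", "y")
  k <- 0L
  in_group <- FALSE
  for (ch in chars) {
    if (ch %in% vowels) {
      if (!in_group) k <- k + 1L
      in_group <- TRUE
    } else {
      in_group <- FALSE
    }
  }
  n <- length(chars)
  if (k > 1L && chars[n] == "e" &&
      !(n >= 2 && chars[n - 1] == "l")) {
    k <- k - 1L
  }
  max(k, 1L)
}

# -- independent brute-force feature extractor (direct enumeration)
oracle_features <- function(transcript, labeling,
                            pos_lexicon = NULL, neg_lexicon = NULL) {
  if (is.null(pos_lexicon)) {
    pos_lexicon <- readLines(system.file("extdata", "sentiment_positive.txt",
                                         package = "speechmarkers"))
    neg_lexicon <- readLines(system.file("extdata", "sentiment_negative.txt",
                                         package = "speechmarkers"))
  }
  tk <- transcript$tokens
  tk <- tk[order(tk$start, tk$end), ]
  role <- ifelse(tk$speaker_raw == labeling$clinician_label,
                 "clinician", "participant")
  # enumerate turns with an explicit loop
  turn_of <- integer(nrow(tk))
  turn_of[1] <- 1L
  for (i in seq_len(nrow(tk))[-1]) {
    turn_of[i] <- if (role[i] == role[i - 1]) turn_of[i - 1]
                  else turn_of[i - 1] + 1L
  }
  n_turns <- max(turn_of)
  t_role <- character(n_turns); t_start <- numeric(n_turns)
  t_end <- numeric(n_turns); t_words <- integer(n_turns)
  t_syll <- numeric(n_turns); t_pos <- numeric(n_turns)
  t_neg <- numeric(n_turns)
  intra <- numeric(0)
  for (t in seq_len(n_turns)) {
    idx <- which(turn_of == t)
    t_role[t] <- role[idx[1]]
    t_start[t] <- tk$start[idx[1]]
    t_end[t] <- tk$end[idx[length(idx)]]
    t_words[t] <- length(idx)
    syl <- 0
    npos <- 0; nneg <- 0
    for (i in idx) {
      syl <- syl + oracle_syllables(tk$text[i])
      w <- tolower(gsub("[^a-z0-9']+", "", tolower(tk$text[i])))
      if (w %in% pos_lexicon) npos <- npos + 1
      if (w %in% neg_lexicon) nneg <- nneg + 1
    }
    t_syll[t] <- syl
    t_pos[t] <- npos / length(idx)
    t_neg[t] <- nneg / length(idx)
    if (t_role[t] == "participant" && length(idx) > 1) {
      for (j in seq_along(idx)[-1]) {
        g <- tk$start[idx[j]] - tk$end[idx[j - 1]]
        intra <- c(intra, max(g, 0))
      }
    }
  }
  p <- which(t_role == "participant")
  spans <- t_end[p] - t_start[p]
  total_span <- sum(spans)
  pre <- numeric(0); n_int <- 0L
  for (t in p) {
    if (t > 1 && t_role[t - 1] == "clinician") {
      g <- t_start[t] - t_end[t - 1]
      if (g < 0) n_int <- n_int + 1L else pre <- c(pre, g)
    }
  }
  wsum <- sum(t_words[p])
  feats <- c(
    speech_length_minutes = total_span / 60,
    speech_length_words = wsum,
    speaker_percentage = 100 * total_span / transcript$file_duration,
    turn_length_minutes_mean = mean(spans) / 60,
    turn_length_words_mean = mean(t_words[p]),
    words_per_minute = if (total_span > 0) wsum / (total_span / 60)
                       else NA_real_,
    syllables_per_minute = if (total_span > 0)
      sum(t_syll[p]) / (total_span / 60) else NA_real_,
    word_pause_mean = if (length(intra) >= 1) mean(intra) else NA_real_,
    word_pause_variability = if (length(intra) >= 2) sd(intra) else NA_real_,
    pre_turn_pause_mean = if (length(pre) >= 1) mean(pre) else NA_real_,
    sentiment_positive = sum(t_pos[p] * t_words[p]) / wsum,
    sentiment_negative = sum(t_neg[p] * t_words[p]) / wsum
  )
  list(features = feats, n_interruptions = n_int)
}

# -- independent Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    val <- m * p[ord[i]] / i
    running_min <- min(running_min, val)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# -- random 2-speaker token stream (<= 50 words) for oracle equivalence
random_stream <- function(seed, max_words = 50) {
  set.seed(seed)
  n <- sample(3:max_words, 1)
  # alternate speaker blocks of random length
  speaker <- character(0)
  who <- sample(c("A", "B"), 1)
  while (length(speaker) < n) {
    len <- sample(1:6, 1)
    speaker <- c(speaker, rep(who, len))
    who <- if (who == "A") "B" else "A"
  }
  speaker <- speaker[1:n]
  words <- replicate(n, paste(sample(letters, sample(2:8, 1),
                                     replace = TRUE), collapse = ""))
  durations <- runif(n, 0.05, 0.6)
  # gaps may be negative (timing jitter / interruptions)
  gaps <- runif(n - 1, -0.3, 1.2)
  start <- numeric(n); end <- numeric(n)
  start[1] <- runif(1, 0, 2)
  end[1] <- start[1] + durations[1]
  for (i in 2:n) {
    start[i] <- max(end[i - 1] + gaps[i - 1], start[i - 1] + 1e-3)
    end[i] <- start[i] + durations[i]
  }
  tokens <- data.frame(text = words, start = start, end = end,
                       speaker_raw = speaker, stringsAsFactors = FALSE)
  new_transcript(tokens, interview_id = paste0("stream", seed),
                 file_duration = max(end) + runif(1, 0.5, 5))
}
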