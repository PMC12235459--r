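# Speaker identification: which raw diarization label is the clinician?
# Structured-interview prompts are predictable, so the speaker whose turns
# look most like the expected prompt list is taken to be the clinician.

#' Bundled structured-interview prompt set
#'
#' Generic paraphrases of the kinds of questions a clinician asks while
#' administering a structured psychiatric symptom interview (sleep,
#' appetite, mood, unusual experiences, ...). These are not the verbatim
#' text of any proprietary instrument; the identification method only
#' needs a known prompt list.
#'
#' @param path optional path to a plain-text file, one prompt per line,
#'   overriding the bundled set.
#' @return Character vector of prompts (at least 5).
#' @export
default_prompts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "prompts.txt", package = "speechmarkers")
  }
  prompts <- readLines(path, warn = FALSE)
  prompts <- trimws(prompts)
  prompts <- prompts[nzchar(prompts) & !startsWith(prompts, "#")]
  if (length(prompts) < 5) {
    stop("prompt set must contain at least 5 prompts")
  }
  prompts
}

#' Cosine similarity between two weighted term vectors
#'
#' @param u,v numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return `dot(u, v) / (|u| |v|)`; in `[0, 1]` for non-negative weights.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero vector")
  }
  sum(u * v) / (nu * nv)
}

#' Deterministic lexical text vectorizer (tf-idf)
#'
#' The default text backend: term-frequency vectors over the union
#' vocabulary of all texts passed in one call, weighted by smoothed
#' inverse document frequency computed on that same small corpus
#' (lowercased, punctuation stripped). Any function with the same
#' contract — `function(texts)` returning one numeric row per text,
#' deterministically — can be substituted, e.g. a sentence-embedding
#' model.
#'
#' @return A vectorizer function: `character vector -> numeric matrix`.
#' @export
lexical_vectorizer <- function() {
  function(texts) {
    token_lists <- lapply(texts, function(t) {
      w <- clean_word(strsplit(trimws(t), "\\s+")[[1]])
      w[nzchar(w)]
    })
    vocab <- sort(unique(unlist(token_lists)))
    n_doc <- length(texts)
    mat <- matrix(0, nrow = n_doc, ncol = length(vocab),
                  dimnames = list(NULL, vocab))
    if (length(vocab) == 0) {
      return(mat)
    }
    for (i in seq_len(n_doc)) {
      idx <- match(token_lists[[i]], vocab)
      mat[i, ] <- tabulate(idx, nbins = length(vocab))
    }
    df <- colSums(mat > 0)
    idf <- log((1 + n_doc) / (1 + df)) + 1
    sweep(mat, 2, idf, `*`)
  }
}

#' Score one speaker's turns against the expected prompt set
#'
#' For each prompt the maximum cosine similarity over the speaker's turn
#' texts is taken; the score is the mean of these per-prompt maxima. A
#' speaker who covers many distinct prompts therefore scores higher than
#' one who repeats a single prompt.
#'
#' @param turn_texts character vector of the speaker's turn texts.
#' @param prompts character vector of expected prompts.
#' @param vectorizer text backend; see [lexical_vectorizer()].
#' @return Similarity score in `[0, 1]`.
#' @export
score_speaker_against_prompts <- function(turn_texts, prompts,
                                          vectorizer = lexical_vectorizer()) {
  turn_texts <- turn_texts[nzchar(trimws(turn_texts))]
  if (length(turn_texts) == 0) {
    stop("no non-empty turn texts to score")
  }
  stopifnot(length(prompts) >= 1)
  mat <- vectorizer(c(prompts, turn_texts))
  p_idx <- seq_along(prompts)
  t_idx <- length(prompts) + seq_along(turn_texts)
  norms <- sqrt(rowSums(mat^2))
  zero_rows <- norms == 0
  if (any(zero_rows)) {
    warning("text(s) with empty vector treated as similarity 0")
    norms[zero_rows] <- 1 # rows are all-zero, so similarity is 0 anyway
  }
  unit <- mat / norms
  sims <- unit[p_idx, , drop = FALSE] %*% t(unit[t_idx, , drop = FALSE])
  per_prompt_max <- apply(sims, 1, max)
  score <- mean(per_prompt_max)
  min(max(score, 0), 1)
}

#' Identify the clinician and participant speakers
#'
#' Requires exactly two raw speaker labels. Each speaker's turn texts are
#' scored against the prompt set; the higher-scoring speaker is labeled
#' clinician and the other participant. An exact tie is broken
#' deterministically (lexicographically smaller raw label becomes the
#' clinician) and flagged low confidence, as is any margin below
#' `margin_threshold`.
#'
#' @param transcript a [new_transcript()] object with exactly 2 speakers.
#' @param prompts expected prompt texts; defaults to [default_prompts()].
#' @param vectorizer text backend; see [lexical_vectorizer()].
#' @param margin_threshold low-confidence margin (default 0.05).
#' @return An object of class `speaker_labeling` with fields
#'   `clinician_label`, `participant_label`, `clinician_score`,
#'   `participant_score`, `margin`, `low_confidence`.
#' @export
identify_participant <- function(transcript, prompts = default_prompts(),
                                 vectorizer = lexical_vectorizer(),
                                 margin_threshold = 0.05) {
  stopifnot(inherits(transcript, "transcript"))
  labels <- sort(unique(transcript$tokens$speaker_raw))
  if (length(labels) != 2) {
    stop(sprintf("speaker identification needs exactly 2 speakers, found %d",
                 length(labels)))
  }
  texts <- raw_turn_texts(transcript)
  scores <- vapply(labels, function(lb) {
    score_speaker_against_prompts(texts[[lb]], prompts, vectorizer)
  }, numeric(1))
  tie <- scores[1] == scores[2]
  # on a tie, sort order already puts the lexicographically smaller first
  clin <- if (tie) 1L else which.max(scores)
  part <- 3L - clin
  out <- structure(
    list(
      clinician_label = labels[clin],
      participant_label = labels[part],
      clinician_score = unname(scores[clin]),
      participant_score = unname(scores[part]),
      margin = unname(scores[clin] - scores[part]),
      low_confidence = tie || (scores[clin] - scores[part]) < margin_threshold
    ),
    class = "speaker_labeling"
  )
  out
}

#' @export
print.speaker_labeling <- function(x, ...) {
  cat(sprintf(
    "<speaker_labeling: clinician='%s' (%.3f), participant='%s' (%.3f), margin=%.3f%s>\n",
    x$clinician_label, x$clinician_score, x$participant_label,
    x$participant_score, x$margin,
    if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

# turn texts per raw speaker label: maximal same-speaker runs in start order
raw_turn_texts <- function(transcript) {
  tk <- transcript$tokens
  runs <- rle(tk$speaker_raw)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  texts <- mapply(function(a, b) paste(tk$text_clean[a:b], collapse = " "),
                  starts, stops)
  split(texts, runs$values)
}
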