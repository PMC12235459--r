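#' @keywords internal
"_PACKAGE"

# Canonical vocabulary shared across modules ---------------------------------

#' Names of the twelve speech characteristics
#'
#' Order matches the feature table and results output: amount of speech
#' (5 features), rate of speech (2), pause characteristics (3), and
#' emotional sentiment (2).
#'
#' @return Character vector of length 12.
#' @export
speech_feature_names <- function() {
  c(
    "speech_length_minutes", "speech_length_words", "speaker_percentage",
    "turn_length_minutes_mean", "turn_length_words_mean",
    "words_per_minute", "syllables_per_minute",
    "word_pause_mean", "word_pause_variability", "pre_turn_pause_mean",
    "sentiment_positive", "sentiment_negative"
  )
}

#' Accepted study-visit labels
#' @return Character vector of the five visit labels, in study order.
#' @export
visit_levels <- function() {
  c("screening", "baseline", "day14", "day28", "day35")
}

# lowercase, strip everything that is not a letter, digit or apostrophe
clean_word <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9']+", "", x)
}

normalize_visit <- function(x) {
  gsub("[ _-]", "", tolower(trimws(as.character(x))))
}

# Transcript constructor ------------------------------------------------------

#' Construct a transcript object
#'
#' A transcript holds word tokens with start/end times (seconds) and raw
#' diarization speaker labels, sorted by start time.
#'
#' @param tokens data.frame with columns `text`, `start`, `end`,
#'   `speaker_raw`. A `text_clean` column (lowercased, punctuation
#'   stripped) is added if absent.
#' @param interview_id identifier string.
#' @param file_duration recording length in seconds; if `NULL`, derived
#'   as the maximum token end time (recorded in `duration_derived`).
#' @return An object of class `transcript`.
#' @export
new_transcript <- function(tokens, interview_id = "interview",
                           file_duration = NULL) {
  stopifnot(is.data.frame(tokens))
  required <- c("text", "start", "end", "speaker_raw")
  missing_cols <- setdiff(required, names(tokens))
  if (length(missing_cols) > 0) {
    stop("transcript tokens lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tokens) == 0) {
    stop("empty transcript: no word tokens")
  }
  tokens$text <- trimws(as.character(tokens$text))
  if (any(!nzchar(tokens$text))) {
    stop("token ", which(!nzchar(tokens$text))[1], " has empty text")
  }
  tokens$start <- as.numeric(tokens$start)
  tokens$end <- as.numeric(tokens$end)
  if (any(!is.finite(tokens$start)) || any(!is.finite(tokens$end))) {
    stop("non-numeric token timing")
  }
  bad <- which(tokens$end < tokens$start)
  if (length(bad) > 0) {
    stop(sprintf("token %d ('%s') has end %.3f < start %.3f",
                 bad[1], tokens$text[bad[1]],
                 tokens$end[bad[1]], tokens$start[bad[1]]))
  }
  if (any(tokens$start < 0)) {
    stop("negative token start time")
  }
  tokens$speaker_raw <- as.character(tokens$speaker_raw)
  if (!"text_clean" %in% names(tokens)) {
    tokens$text_clean <- clean_word(tokens$text)
  }
  ord <- order(tokens$start, tokens$end)
  tokens <- tokens[ord, , drop = FALSE]
  rownames(tokens) <- NULL
  duration_derived <- is.null(file_duration)
  if (duration_derived) {
    file_duration <- max(tokens$end)
  }
  structure(
    list(
      interview_id = as.character(interview_id),
      tokens = tokens,
      file_duration = as.numeric(file_duration),
      duration_derived = duration_derived,
      n_speakers_raw = length(unique(tokens$speaker_raw))
    ),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript '%s': %d tokens, %d speaker(s), %.1f s>\n",
              x$interview_id, nrow(x$tokens), x$n_speakers_raw,
              x$file_duration))
  invisible(x)
}

# Parsing ---------------------------------------------------------------------

#' Parse a diarized word-timestamped transcript
#'
#' Two dialects are supported. `word_records` is one JSON object per line
#' (`text`, `start`, `end`, `speaker`), optionally preceded by a `_meta`
#' line carrying `interview_id` and `file_duration`; a plain JSON array of
#' the same objects is also accepted. `cloud_json` mimics cloud
#' transcription output: a `results$items` array of pronunciation items
#' (with `start_time`, `end_time`, `speaker_label` and an
#' `alternatives[[1]]$content`) interleaved with punctuation items that
#' carry no timing; punctuation is merged into the preceding word's text
#' and never counted as a word.
#'
#' @param document path to a file, or a character scalar holding the raw
#'   document text.
#' @param dialect `"word_records"` or `"cloud_json"`.
#' @param interview_id identifier; defaults to the file name (without
#'   extension) when `document` is a path, or any id found in the
#'   document itself.
#' @return A [new_transcript()] object with tokens sorted by start time.
#' @export
parse_transcript <- function(document,
                             dialect = c("word_records", "cloud_json"),
                             interview_id = NULL) {
  dialect <- match.arg(dialect)
  is_path <- length(document) == 1 && !grepl("[\n{\\[]", document) &&
    file.exists(document)
  fallback_id <- NULL
  if (is_path) {
    text <- paste(readLines(document, warn = FALSE), collapse = "\n")
    fallback_id <- tools::file_path_sans_ext(basename(document))
  } else {
    text <- paste(document, collapse = "\n")
  }
  if (!nzchar(trimws(text))) {
    stop("empty transcript document")
  }
  out <- if (dialect == "word_records") {
    parse_word_records(text, interview_id)
  } else {
    parse_cloud_json(text, interview_id)
  }
  if (identical(out$interview_id, "interview") && !is.null(fallback_id)) {
    out$interview_id <- fallback_id
  }
  out
}

parse_word_records <- function(text, interview_id) {
  txt <- trimws(text)
  file_duration <- NULL
  if (startsWith(txt, "[")) {
    recs <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) > 0 && grepl("\"_meta\"", lines[1], fixed = TRUE)) {
      meta <- jsonlite::fromJSON(lines[1])[["_meta"]]
      if (!is.null(meta$interview_id) && is.null(interview_id)) {
        interview_id <- meta$interview_id
      }
      if (!is.null(meta$file_duration)) {
        file_duration <- as.numeric(meta$file_duration)
      }
      lines <- lines[-1]
    }
    if (length(lines) == 0) {
      stop("empty transcript: no word records")
    }
    recs <- tryCatch(
      jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                         simplifyDataFrame = TRUE),
      error = function(e) {
        # bulk parse failed: walk the lines to name the offender
        for (i in seq_along(lines)) {
          ok <- tryCatch({jsonlite::fromJSON(lines[i]); TRUE},
                         error = function(e2) FALSE)
          if (!ok) {
            stop(sprintf("malformed word record on line %d: %s",
                         i, lines[i]), call. = FALSE)
          }
        }
        stop("malformed word_records document: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  if (!is.data.frame(recs) || nrow(recs) == 0) {
    stop("empty transcript: no word records")
  }
  if ("word" %in% names(recs) && !"text" %in% names(recs)) {
    recs$text <- recs$word
  }
  missing_cols <- setdiff(c("text", "start", "end", "speaker"), names(recs))
  if (length(missing_cols) > 0) {
    stop("malformed word records: every record needs fields ",
         "text, start, end, speaker (missing: ",
         paste(missing_cols, collapse = ", "), ")")
  }
  incomplete <- which(is.na(recs$text) | is.na(recs$start) |
                        is.na(recs$end) | is.na(recs$speaker))
  if (length(incomplete) > 0) {
    stop(sprintf(
      "malformed word record %d: needs fields text, start, end, speaker",
      incomplete[1]))
  }
  tokens <- data.frame(text = as.character(recs$text),
                       start = as.numeric(recs$start),
                       end = as.numeric(recs$end),
                       speaker_raw = as.character(recs$speaker),
                       stringsAsFactors = FALSE)
  new_transcript(tokens, interview_id = interview_id %||% "interview",
                 file_duration = file_duration)
}

parse_cloud_json <- function(text, interview_id) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed cloud_json document: ",
                         conditionMessage(e), call. = FALSE)
                  })
  items <- doc$results$items
  if (is.null(items)) {
    stop("malformed cloud_json document: no results$items array")
  }
  if (is.null(interview_id)) {
    interview_id <- doc$jobName %||% doc$interview_id %||% "interview"
  }
  file_duration <- doc$file_duration %||% doc$results$file_duration
  texts <- character(0); starts <- numeric(0); ends <- numeric(0)
  speakers <- character(0)
  for (i in seq_along(items)) {
    it <- items[[i]]
    content <- it$alternatives[[1]]$content %||% it$content
    if (is.null(content)) {
      stop(sprintf("malformed cloud_json item %d: no content", i))
    }
    type <- it$type %||% "pronunciation"
    if (identical(type, "punctuation")) {
      # attach to the previous word; a leading punctuation item has no host
      if (length(texts) > 0) {
        texts[length(texts)] <- paste0(texts[length(texts)], content)
      }
      next
    }
    st <- it$start_time %||% it$start
    en <- it$end_time %||% it$end
    sp <- it$speaker_label %||% it$speaker
    if (is.null(st) || is.null(en) || is.null(sp)) {
      stop(sprintf(
        "malformed cloud_json item %d ('%s'): missing timing or speaker",
        i, content))
    }
    texts <- c(texts, as.character(content))
    starts <- c(starts, as.numeric(st))
    ends <- c(ends, as.numeric(en))
    speakers <- c(speakers, as.character(sp))
  }
  if (length(texts) == 0) {
    stop("empty transcript: no pronunciation items")
  }
  tokens <- data.frame(text = texts, start = starts, end = ends,
                       speaker_raw = speakers, stringsAsFactors = FALSE)
  new_transcript(tokens, interview_id = interview_id,
                 file_duration = if (is.null(file_duration)) NULL
                 else as.numeric(file_duration))
}

#' Write a transcript in the word_records dialect
#'
#' One JSON object per line, preceded by a `_meta` line holding the
#' interview id and file duration. Re-parsing the written file yields an
#' identical token list.
#'
#' @param transcript a [new_transcript()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  stopifnot(inherits(transcript, "transcript"))
  esc <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    gsub("\"", "\\\"", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  meta <- sprintf(
    "{\"_meta\":{\"interview_id\":\"%s\",\"file_duration\":%s}}",
    esc(transcript$interview_id), num(transcript$file_duration))
  tk <- transcript$tokens
  lines <- sprintf(
    "{\"text\":\"%s\",\"start\":%s,\"end\":%s,\"speaker\":\"%s\"}",
    esc(tk$text), num(tk$start), num(tk$end), esc(tk$speaker_raw))
  writeLines(c(as.character(meta), lines), path)
  invisible(path)
}

# Clinical table --------------------------------------------------------------

#' Read the clinical table
#'
#' Expects a CSV with header
#' `subject_id,visit,age,sex,race,panss_p,panss_n`. Visit labels are
#' matched case-insensitively (spaces/underscores ignored) against the
#' five-visit vocabulary. Rows with missing PANSS subscale scores are
#' retained but flagged `usable = FALSE`; they are excluded from
#' association fitting downstream.
#'
#' @param path CSV file path.
#' @return data.frame with normalized columns plus a logical `usable`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("subject_id", "visit", "age", "sex", "race",
                "panss_p", "panss_n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  visit <- normalize_visit(df$visit)
  bad_visit <- which(!visit %in% visit_levels())
  if (length(bad_visit) > 0) {
    stop(sprintf(
      "row %d: unknown visit '%s'; accepted labels: %s",
      bad_visit[1], df$visit[bad_visit[1]],
      paste(visit_levels(), collapse = ", ")))
  }
  parse_num <- function(col, name, allow_na = FALSE) {
    raw <- trimws(df[[col]])
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out) & nzchar(raw))
    if (length(bad) > 0) {
      stop(sprintf("row %d: non-numeric %s '%s'", bad[1], name, raw[bad[1]]))
    }
    if (!allow_na && any(!nzchar(raw))) {
      stop(sprintf("row %d: missing %s", which(!nzchar(raw))[1], name))
    }
    out
  }
  age <- parse_num("age", "age")
  panss_p <- parse_num("panss_p", "panss_p score", allow_na = TRUE)
  panss_n <- parse_num("panss_n", "panss_n score", allow_na = TRUE)
  for (sc in list(list(v = panss_p, n = "panss_p"),
                  list(v = panss_n, n = "panss_n"))) {
    out_of_range <- which(!is.na(sc$v) & (sc$v < 7 | sc$v > 49))
    if (length(out_of_range) > 0) {
      stop(sprintf("row %d: %s %g outside the valid subscale range [7, 49]",
                   out_of_range[1], sc$n, sc$v[out_of_range[1]]))
    }
  }
  sex <- tolower(trimws(df$sex))
  bad_sex <- which(!sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    stop(sprintf("row %d: sex must be male or female, got '%s'",
                 bad_sex[1], df$sex[bad_sex[1]]))
  }
  race <- tolower(trimws(df$race))
  race[!race %in% c("black", "white")] <- "other"
  out <- data.frame(
    subject_id = trimws(df$subject_id),
    visit = visit,
    age = age,
    sex = sex,
    race = race,
    panss_p = panss_p,
    panss_n = panss_n,
    stringsAsFactors = FALSE
  )
  out$usable <- !is.na(out$panss_p) & !is.na(out$panss_n)
  out
}

#' Write a feature table CSV
#'
#' Missing features are written as empty cells, never as zero.
#'
#' @param feature_table data.frame of per-interview feature rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(feature_table, path) {
  utils::write.csv(feature_table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame; empty cells become `NA`.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
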