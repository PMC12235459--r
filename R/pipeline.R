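# Pipeline orchestration: simulate -> extract -> analyze, with per-file
# failure isolation and a manifest recording what was run. These
# functions are the programmatic interface; a thin command-line wrapper
# over them ships in inst/cli/.

#' Read a pipeline configuration file
#'
#' YAML with optional keys `seed`, `n_subjects`, `out`, `prompts`,
#' `fdr_scope`, `rate_definition`, `significance`,
#' `adjust_interview_length`, `interruption_prob`, `prompt_dropout`,
#' `missing_clinical_n`. Unknown keys are rejected so typos surface.
#'
#' @param path YAML file path, or `NULL` for an empty config.
#' @return named list.
#' @export
read_pipeline_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "n_subjects", "out", "prompts", "fdr_scope",
             "rate_definition", "significance", "adjust_interview_length",
             "interruption_prob", "prompt_dropout", "missing_clinical_n")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic dataset to disk
#'
#' @param out output directory.
#' @param seed integer seed.
#' @param n_subjects cohort size.
#' @param config named list of extra [cohort_spec()] overrides
#'   (`interruption_prob`, `prompt_dropout`, `missing_clinical_n`).
#' @return the output directory, invisibly; writes transcripts (one
#'   word_records file per interview, under a directory per visit),
#'   `clinical.csv`, `truth.json` and `manifest.json`.
#' @export
cmd_simulate <- function(out, seed = 1, n_subjects = 150, config = list()) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("usage error: n_subjects must be a positive integer")
  }
  spec_args <- list(n_subjects = as.integer(n_subjects),
                    seed = as.integer(seed))
  for (k in c("interruption_prob", "prompt_dropout", "missing_clinical_n")) {
    if (!is.null(config[[k]])) spec_args[[k]] <- config[[k]]
  }
  spec <- do.call(cohort_spec, spec_args)
  ds <- generate_dataset(spec, dir = out)
  manifest <- list(
    command = "simulate", seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_interviews = length(ds$transcripts),
    visits = spec$visits,
    outputs = list(transcripts = file.path(out, "transcripts"),
                   clinical = file.path(out, "clinical.csv"),
                   truth = file.path(out, "truth.json")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_manifest(manifest, file.path(out, "manifest.json"))
  invisible(out)
}

#' Extract features from a directory of transcripts
#'
#' Processes every `.jsonl`/`.json` file under `transcript_dir`
#' (recursively): parse, identify the participant, extract the twelve
#' features. Failures are logged per file and never abort the batch. The
#' manifest records input checksums and per-interview status, with
#' `processed + failed = seen`.
#'
#' @param transcript_dir directory of word_records transcripts.
#' @param out output directory for `features.csv` and `manifest.json`.
#' @param prompts prompt texts for speaker identification.
#' @param dialect transcript dialect.
#' @param rate_definition rate pooling; see [extract_features()].
#' @param verbose print a status line per file to stderr.
#' @return the feature table, invisibly.
#' @export
cmd_extract <- function(transcript_dir, out, prompts = default_prompts(),
                        dialect = "word_records",
                        rate_definition = "pooled", verbose = FALSE) {
  files <- list.files(transcript_dir, pattern = "\\.jsonl?$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0) {
    stop("no transcript files found under ", transcript_dir)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sentiment <- lexicon_sentiment()
  vectorizer <- lexical_vectorizer()
  status <- vector("list", length(files))
  rows <- list()
  for (i in seq_along(files)) {
    f <- files[i]
    id <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      tr <- parse_transcript(f, dialect = dialect)
      lab <- identify_participant(tr, prompts, vectorizer)
      fv <- extract_features(tr, lab, sentiment,
                             rate_definition = rate_definition)
      row <- as_feature_row(fv)
      row$clinician_label <- lab$clinician_label
      row$low_confidence <- lab$low_confidence
      rows[[length(rows) + 1]] <- row
      list(interview = id, status = "processed")
    }, error = function(e) {
      list(interview = id, status = "failed", reason = conditionMessage(e))
    })
    status[[i]] <- res
    if (verbose) {
      message(sprintf("[%d/%d] %s: %s", i, length(files), id, res$status))
    }
  }
  feature_table <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  n_processed <- sum(vapply(status, function(s) s$status == "processed",
                            logical(1)))
  manifest <- list(
    command = "extract",
    inputs = data.frame(file = files,
                        md5 = unname(tools::md5sum(files)),
                        stringsAsFactors = FALSE),
    interviews = status,
    counts = list(seen = length(files), processed = n_processed,
                  failed = length(files) - n_processed),
    outputs = list(features = file.path(out, "features.csv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(feature_table)) {
    write_feature_table(feature_table, file.path(out, "features.csv"))
  }
  write_manifest(manifest, file.path(out, "manifest.json"))
  invisible(feature_table)
}

#' Extract features from an in-memory synthetic dataset
#'
#' Runs speaker identification and feature extraction over every
#' transcript of a [generate_dataset()] result without touching disk.
#'
#' @param ds a `synthetic_dataset`.
#' @param identify if `FALSE`, the ground-truth speaker labels from the
#'   dataset are used instead of running identification.
#' @param rate_definition rate pooling; see [extract_features()].
#' @return feature table data.frame, one row per interview, with
#'   `subject_id`, `visit` and a `clinician_correct` flag when
#'   identification was run.
#' @export
extract_dataset_features <- function(ds, identify = TRUE,
                                     rate_definition = "pooled") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  sentiment <- lexicon_sentiment()
  vectorizer <- lexical_vectorizer()
  rows <- vector("list", length(ds$transcripts))
  for (i in seq_along(ds$transcripts)) {
    tr <- ds$transcripts[[i]]
    truth_clin <- ds$truth$clinician_label[i]
    if (identify) {
      lab <- identify_participant(tr, ds$spec$prompts, vectorizer)
    } else {
      labels <- unique(tr$tokens$speaker_raw)
      lab <- list(clinician_label = truth_clin,
                  participant_label = setdiff(labels, truth_clin))
    }
    fv <- extract_features(tr, lab, sentiment,
                           rate_definition = rate_definition)
    row <- as_feature_row(fv)
    row$subject_id <- ds$truth$subject_id[i]
    row$visit <- ds$truth$visit[i]
    row$clinician_correct <- identical(lab$clinician_label, truth_clin)
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Run the association analysis on extracted features
#'
#' @param feature_csv path to a feature table CSV (from [cmd_extract()]).
#' @param clinical_csv path to the clinical CSV.
#' @param out output directory for `results.csv`, `report.json`.
#' @param config a [suite_config()].
#' @return the `association_suite` object, invisibly.
#' @export
cmd_analyze <- function(feature_csv, clinical_csv, out,
                        config = suite_config()) {
  ft <- read_feature_table(feature_csv)
  cl <- read_clinical_table(clinical_csv)
  suite <- run_association_suite(ft, cl, config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(suite$results, file.path(out, "results.csv"),
                   row.names = FALSE, na = "")
  report <- list(
    counts = suite$counts,
    config = unclass(config),
    results = suite$results,
    distributions = suite$distributions,
    demographics = suite$demographics,
    baseline_ols = if (!is.null(suite$baseline_ols)) {
      suite$baseline_ols$results
    } else NULL
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(suite)
}

#' Run the full pipeline: simulate, extract, analyze
#'
#' @param out working directory for all stages.
#' @param seed integer seed driving all randomness.
#' @param n_subjects cohort size.
#' @param config a [suite_config()] for the analysis stage.
#' @param sim_config extra generator overrides (see [cmd_simulate()]).
#' @return the `association_suite` from the analysis stage, invisibly.
#' @export
run_pipeline <- function(out, seed = 1, n_subjects = 150,
                         config = suite_config(), sim_config = list()) {
  cmd_simulate(file.path(out, "data"), seed = seed,
               n_subjects = n_subjects, config = sim_config)
  cmd_extract(file.path(out, "data", "transcripts"),
              out = file.path(out, "features"),
              rate_definition = config$rate_definition)
  cmd_analyze(file.path(out, "features", "features.csv"),
              file.path(out, "data", "clinical.csv"),
              out = file.path(out, "analysis"),
              config = config)
}
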