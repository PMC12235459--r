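# Statistical layer: distribution summaries, demographic screens,
# mixed-effects association models with FDR control, and the
# baseline-averaged OLS sensitivity analysis.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, returned in input order. Thin validated
#' wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of raw p-values, each in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Distribution summary for one feature
#'
#' Mean, sample standard deviation and excess kurtosis (fourth
#' standardized moment minus 3, bias-uncorrected). A kurtosis screen in
#' roughly `[-1, 1]` supports the use of parametric tests downstream.
#'
#' @param values numeric vector with at least 4 finite values.
#' @param feature feature name carried into the output.
#' @return data.frame row: `feature`, `mean`, `sd`, `excess_kurtosis`, `n`.
#' @export
summarize_distribution <- function(values, feature = "feature") {
  x <- values[is.finite(values)]
  if (length(x) < 4) {
    stop("distribution summary needs at least 4 finite values, got ",
         length(x))
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    stop("kurtosis undefined for constant values (feature '", feature, "')")
  }
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  data.frame(feature = feature, mean = m, sd = s,
             excess_kurtosis = m4 / m2^2 - 3, n = length(x),
             stringsAsFactors = FALSE)
}

# Build the fixed-effect part of the model, dropping demographic terms
# that are constant in the data at hand (a single-sex subset, say).
fixed_terms <- function(data) {
  terms <- "feature"
  if (length(unique(data$age)) > 1) terms <- c(terms, "age")
  if (length(unique(data$sex)) > 1) terms <- c(terms, "sex")
  if (length(unique(data$race)) > 1) terms <- c(terms, "race")
  terms
}

#' Mixed-effects association between one feature and a clinical score
#'
#' Fits `score ~ feature + age + sex + race + (1 | subject) + (1 | visit)`
#' by REML with independent (crossed) random intercepts for subject and
#' visit, and returns the feature coefficient with a Satterthwaite
#' t-test. The effect size is partial eta-squared computed as
#' `t^2 / (t^2 + df)` with the Satterthwaite denominator degrees of
#' freedom. Rows with missing values in any modeled column are dropped
#' (complete-case) and counted.
#'
#' @param feature_values,scores numeric vectors.
#' @param age numeric; `sex`, `race` character/factor covariates.
#' @param subject,visit grouping identifiers.
#' @param feature_name,scale labels carried into the result.
#' @param significance FDR threshold used for the direction label.
#' @return An object of class `association_result` (also a one-row
#'   data.frame): `feature`, `scale`, `beta`, `se`, `t`, `df`, `p_raw`,
#'   `p_fdr` (equal to `p_raw` for a single fit), `partial_eta_sq`,
#'   `direction`, `n_obs`, `n_subjects`, `n_dropped`.
#' @export
fit_mixed_association <- function(feature_values, scores, age, sex, race,
                                  subject, visit,
                                  feature_name = "feature",
                                  scale = "score",
                                  significance = 0.05) {
  data <- data.frame(
    score = as.numeric(scores), feature = as.numeric(feature_values),
    age = as.numeric(age), sex = as.factor(sex), race = as.factor(race),
    subject = as.factor(subject), visit = as.factor(visit)
  )
  complete <- stats::complete.cases(data)
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (nrow(data) < 4 || length(unique(data$subject)) < 2) {
    stop("too few complete observations to fit association for '",
         feature_name, "'")
  }
  if (stats::var(data$feature) == 0) {
    stop("feature '", feature_name, "' has zero variance; model is singular")
  }
  fml <- stats::as.formula(paste(
    "score ~", paste(fixed_terms(data), collapse = " + "),
    "+ (1 | subject) + (1 | visit)"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore"))
  ))
  coefs <- stats::coef(summary(fit))
  if (!"feature" %in% rownames(coefs)) {
    stop("model for '", feature_name, "' did not estimate the feature term")
  }
  row <- coefs["feature", ]
  beta <- unname(row["Estimate"])
  se <- unname(row["Std. Error"])
  tval <- unname(row["t value"])
  df <- unname(row["df"])
  p_raw <- unname(row["Pr(>|t|)"])
  if (!is.finite(df) || df < 1) {
    # Satterthwaite collapses when the residual variance is (near) zero;
    # fall back to the classical residual degrees of freedom
    df <- nrow(data) - nrow(coefs)
    p_raw <- 2 * stats::pt(-abs(tval), df)
  }
  p_raw <- min(max(p_raw, .Machine$double.xmin), 1)
  eta <- tval^2 / (tval^2 + df)
  out <- data.frame(
    feature = feature_name, scale = scale,
    beta = beta, se = se, t = tval, df = df,
    p_raw = p_raw, p_fdr = p_raw,
    partial_eta_sq = eta,
    direction = direction_label(beta, p_raw, significance),
    n_obs = nrow(data),
    n_subjects = length(unique(data$subject)),
    n_dropped = n_dropped,
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

direction_label <- function(beta, p_fdr, significance) {
  if (is.na(p_fdr) || p_fdr >= significance) "ns"
  else if (beta > 0) "+" else "-"
}

#' Demographic screen of features at the screening visit
#'
#' Per feature: Pearson correlation (r, R-squared, p) with age; Welch
#' two-sample t-tests comparing feature values across sex
#' (female vs male) and race (black vs white; other categories excluded
#' from that contrast). A test whose smaller group has fewer than 3
#' subjects is skipped with a note.
#'
#' @param data one row per subject (screening visit), with the feature
#'   columns plus `age`, `sex`, `race`.
#' @param feature_cols feature column names; default the 12 canonical
#'   names present in `data`.
#' @return data.frame, one row per feature x test.
#' @export
demographic_screen <- function(data,
                               feature_cols = intersect(speech_feature_names(),
                                                        names(data))) {
  stopifnot(length(feature_cols) >= 1)
  rows <- list()
  for (f in feature_cols) {
    x <- data[[f]]
    ok <- is.finite(x) & is.finite(data$age)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(data$age[ok]) > 0) {
      ct <- stats::cor.test(x[ok], data$age[ok], method = "pearson")
      r <- unname(ct$estimate)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, test = "age_pearson", statistic = unname(ct$statistic),
        estimate = r, r_squared = r^2, group1_mean = NA_real_,
        group2_mean = NA_real_, p = ct$p.value, n = sum(ok), note = "",
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, test = "age_pearson", statistic = NA_real_,
        estimate = NA_real_, r_squared = NA_real_, group1_mean = NA_real_,
        group2_mean = NA_real_, p = NA_real_, n = sum(ok),
        note = "skipped: insufficient data", stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- welch_row(f, x, data$sex, "female", "male",
                                          "sex_ttest")
    rows[[length(rows) + 1]] <- welch_row(f, x, data$race, "black", "white",
                                          "race_ttest")
  }
  do.call(rbind, rows)
}

welch_row <- function(f, x, group, g1, g2, test_name) {
  a <- x[group == g1 & is.finite(x)]
  b <- x[group == g2 & is.finite(x)]
  if (length(a) < 3 || length(b) < 3) {
    return(data.frame(
      feature = f, test = test_name, statistic = NA_real_,
      estimate = NA_real_, r_squared = NA_real_,
      group1_mean = if (length(a)) mean(a) else NA_real_,
      group2_mean = if (length(b)) mean(b) else NA_real_,
      p = NA_real_, n = length(a) + length(b),
      note = sprintf("skipped: group with < 3 subjects (%s=%d, %s=%d)",
                     g1, length(a), g2, length(b)),
      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(a, b) # Welch by default
  data.frame(
    feature = f, test = test_name, statistic = unname(tt$statistic),
    estimate = mean(a) - mean(b), r_squared = NA_real_,
    group1_mean = mean(a), group2_mean = mean(b),
    p = tt$p.value, n = length(a) + length(b), note = "",
    stringsAsFactors = FALSE)
}

#' Baseline-averaged OLS sensitivity analysis
#'
#' Averages each feature and each score over the screening and baseline
#' visits per subject (subjects with only one of the two visits use that
#' single value, flagged in `n_single_visit`), then fits, per feature,
#' an ordinary least squares regression of the averaged score on the
#' averaged feature plus age, sex and race. FDR correction is applied
#' across the feature family within each scale. Because there are no
#' repeated measures, these estimates are unaffected by symptom change
#' over time.
#'
#' @param data joined per-interview rows: `subject_id`, `visit`, the
#'   feature columns, `panss_p`, `panss_n`, `age`, `sex`, `race`.
#' @param feature_cols feature column names.
#' @param scales score columns to model (default both subscales).
#' @param significance FDR threshold for the direction label.
#' @return list with `results` (one row per feature x scale) and counts
#'   `n_subjects`, `n_single_visit`.
#' @export
baseline_average_ols <- function(data,
                                 feature_cols = intersect(
                                   speech_feature_names(), names(data)),
                                 scales = c("panss_p", "panss_n"),
                                 significance = 0.05) {
  sub <- data[data$visit %in% c("screening", "baseline"), , drop = FALSE]
  if (nrow(sub) == 0) stop("no screening/baseline rows")
  agg_cols <- c(feature_cols, scales, "age")
  by_subject <- split(sub, sub$subject_id)
  rows <- lapply(by_subject, function(d) {
    out <- d[1, c("subject_id", "sex", "race"), drop = FALSE]
    for (cc in agg_cols) out[[cc]] <- mean(d[[cc]], na.rm = TRUE)
    out$single_visit <- length(unique(d$visit)) < 2
    out
  })
  avg <- do.call(rbind, rows)
  avg[sapply(avg, is.nan)] <- NA
  usable <- stats::complete.cases(avg[, c(scales, "age"), drop = FALSE])
  avg <- avg[usable, , drop = FALSE]
  if (nrow(avg) < 10) {
    stop("baseline-averaged OLS needs at least 10 usable subjects, got ",
         nrow(avg))
  }
  res <- list()
  for (sc in scales) {
    for (f in feature_cols) {
      d <- data.frame(score = avg[[sc]], feature = avg[[f]], age = avg$age,
                      sex = as.factor(avg$sex), race = as.factor(avg$race))
      d <- d[stats::complete.cases(d), , drop = FALSE]
      fml <- stats::as.formula(paste("score ~",
                                     paste(fixed_terms(d), collapse = " + ")))
      fit <- stats::lm(fml, data = d)
      co <- stats::coef(summary(fit))["feature", ]
      res[[length(res) + 1]] <- data.frame(
        feature = f, scale = toupper(gsub("panss_", "PANSS-", sc)),
        beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
        t = unname(co["t value"]), p_raw = unname(co["Pr(>|t|)"]),
        n_obs = nrow(d), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)
  res$p_raw <- pmin(pmax(res$p_raw, .Machine$double.xmin), 1)
  res$p_fdr <- NA_real_
  for (sc in unique(res$scale)) {
    idx <- res$scale == sc
    res$p_fdr[idx] <- bh_fdr(res$p_raw[idx])
  }
  res$direction <- mapply(direction_label, res$beta, res$p_fdr,
                          MoreArgs = list(significance = significance))
  list(results = res, n_subjects = nrow(avg),
       n_single_visit = sum(avg$single_visit))
}

#' Configuration for the association suite
#'
#' @param fdr_scope `"per_scale"` (FDR within each 12-test family; the
#'   default) or `"pooled"` (one 24-test family).
#' @param significance FDR threshold for calling a direction (default
#'   0.05).
#' @param rate_definition passed through to extraction when the pipeline
#'   drives it; `"pooled"` or `"per_turn"`.
#' @param adjust_interview_length if `TRUE`, each feature is residualized
#'   on `file_duration` before modeling (requires a `file_duration`
#'   column in the feature table).
#' @return list of class `suite_config`.
#' @export
suite_config <- function(fdr_scope = c("per_scale", "pooled"),
                         significance = 0.05,
                         rate_definition = c("pooled", "per_turn"),
                         adjust_interview_length = FALSE) {
  structure(list(
    fdr_scope = match.arg(fdr_scope),
    significance = significance,
    rate_definition = match.arg(rate_definition),
    adjust_interview_length = isTRUE(adjust_interview_length)
  ), class = "suite_config")
}

#' Run the full association suite
#'
#' Joins the per-interview feature table with the clinical table on
#' `(subject_id, visit)`, fits one mixed-effects association per feature
#' per subscale (12 x 2), applies Benjamini-Hochberg FDR within each
#' family, and also returns distribution summaries across all interviews
#' and the screening-visit demographic screen.
#'
#' @param feature_table data.frame with `interview_id` or
#'   `subject_id`/`visit` columns plus the 12 feature columns. If only
#'   `interview_id` of the form `<subject>_<visit>` is present, subject
#'   and visit are recovered from it.
#' @param clinical_table data.frame from [read_clinical_table()].
#' @param config a [suite_config()].
#' @return list of class `association_suite`: `results` (24 rows),
#'   `distributions`, `demographics`, `baseline_ols` (or `NULL` if it
#'   could not be fit), and `counts`.
#' @export
run_association_suite <- function(feature_table, clinical_table,
                                  config = suite_config()) {
  ft <- feature_table
  if (!all(c("subject_id", "visit") %in% names(ft))) {
    if (!"interview_id" %in% names(ft)) {
      stop("feature table needs subject_id/visit or interview_id columns")
    }
    parts <- strsplit(as.character(ft$interview_id), "_(?=[^_]+$)",
                      perl = TRUE)
    ft$subject_id <- vapply(parts, `[`, character(1), 1)
    ft$visit <- vapply(parts, `[`, character(1), 2)
  }
  ft$visit <- normalize_visit(ft$visit)
  cl <- clinical_table
  if (!"usable" %in% names(cl)) {
    cl$usable <- !is.na(cl$panss_p) & !is.na(cl$panss_n)
  }
  joined <- merge(ft, cl, by = c("subject_id", "visit"))
  if (nrow(joined) == 0) {
    stop("join of feature and clinical tables produced zero rows")
  }
  feature_cols <- intersect(speech_feature_names(), names(joined))
  if (length(feature_cols) == 0) stop("no recognized feature columns")

  if (config$adjust_interview_length) {
    if (!"file_duration" %in% names(joined)) {
      stop("interview-length adjustment requires a file_duration column")
    }
    for (f in feature_cols) {
      ok <- is.finite(joined[[f]]) & is.finite(joined$file_duration)
      if (sum(ok) > 3) {
        r <- stats::resid(stats::lm(joined[[f]][ok] ~
                                      joined$file_duration[ok]))
        joined[[f]][ok] <- r + mean(joined[[f]][ok])
      }
    }
  }

  usable <- joined[joined$usable, , drop = FALSE]
  scales <- c(panss_p = "PANSS-P", panss_n = "PANSS-N")
  results <- list()
  for (sc in names(scales)) {
    for (f in feature_cols) {
      results[[length(results) + 1]] <- fit_mixed_association(
        usable[[f]], usable[[sc]], usable$age, usable$sex, usable$race,
        usable$subject_id, usable$visit,
        feature_name = f, scale = scales[[sc]],
        significance = config$significance)
    }
  }
  results <- do.call(rbind, results)
  if (config$fdr_scope == "pooled") {
    results$p_fdr <- bh_fdr(results$p_raw)
  } else {
    for (sc in unique(results$scale)) {
      idx <- results$scale == sc
      results$p_fdr[idx] <- bh_fdr(results$p_raw[idx])
    }
  }
  results$direction <- mapply(direction_label, results$beta, results$p_fdr,
                              MoreArgs = list(
                                significance = config$significance))

  distributions <- do.call(rbind, lapply(feature_cols, function(f) {
    x <- joined[[f]]
    if (sum(is.finite(x)) >= 4 && stats::sd(x[is.finite(x)]) > 0) {
      summarize_distribution(x, f)
    } else {
      data.frame(feature = f, mean = NA_real_, sd = NA_real_,
                 excess_kurtosis = NA_real_, n = sum(is.finite(x)),
                 stringsAsFactors = FALSE)
    }
  }))

  screening <- joined[joined$visit == "screening", , drop = FALSE]
  demographics <- if (nrow(screening) >= 3) {
    demographic_screen(screening, feature_cols)
  } else NULL

  baseline <- tryCatch(
    baseline_average_ols(joined[joined$usable, , drop = FALSE], feature_cols,
                         significance = config$significance),
    error = function(e) NULL)

  structure(list(
    results = results,
    distributions = distributions,
    demographics = demographics,
    baseline_ols = baseline,
    counts = list(
      n_feature_rows = nrow(ft),
      n_clinical_rows = nrow(cl),
      n_joined = nrow(joined),
      n_usable = nrow(usable),
      n_missing_clinical = nrow(joined) - nrow(usable)
    ),
    config = config
  ), class = "association_suite")
}

#' @export
print.association_suite <- function(x, ...) {
  cat(sprintf(
    "<association_suite: %d models, %d/%d interviews usable>\n",
    nrow(x$results), x$counts$n_usable, x$counts$n_joined))
  cols <- c("feature", "scale", "beta", "partial_eta_sq", "p_raw", "p_fdr",
            "direction")
  df <- x$results[, cols]
  df$beta <- signif(df$beta, 3)
  df$partial_eta_sq <- signif(df$partial_eta_sq, 2)
  df$p_raw <- signif(df$p_raw, 2)
  df$p_fdr <- signif(df$p_fdr, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Table-shaped direction matrix from an association suite
#'
#' @param suite an `association_suite`.
#' @return data.frame, one row per feature, with per-scale direction,
#'   beta, partial eta-squared and p-value columns.
#' @export
direction_matrix <- function(suite) {
  res <- suite$results
  out <- NULL
  for (sc in unique(res$scale)) {
    d <- res[res$scale == sc,
             c("feature", "direction", "beta", "partial_eta_sq", "p_fdr")]
    names(d)[-1] <- paste0(c("direction_", "beta_", "eta_", "p_fdr_"),
                           gsub("PANSS-", "", sc))
    out <- if (is.null(out)) d else merge(out, d, by = "feature", sort = FALSE)
  }
  out
}
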