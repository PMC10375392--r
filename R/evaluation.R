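# Evaluation: the feasibility-trial analysis.  Trial-level confusion
# counts and sensitivity/specificity pooled over all scenarios, selection
# error tallies (correct / incorrect / missed per trial), paired timing
# comparison against an external comparator tool, and 5-point Likert survey
# summaries with an interpretation banding.

#' Construct one trial record
#'
#' One participant x scenario observation: the conditions the rater
#' selected, the intended (ground-truth) conditions of the scenario, the
#' true and predicted multimorbidity labels, and optional completion times
#' for the screening app and the comparator tool.
#'
#' @param participant_id,scenario_id Identifiers.
#' @param selected,intended Character vectors of condition ids.
#' @param truth_multimorbid,predicted_multimorbid Logical labels.
#' @param mmapp_time_s,comparator_time_s Optional nonnegative seconds.
#' @return A `qcs_trial` list.
#' @export
new_trial_record <- function(participant_id, scenario_id,
                             selected, intended,
                             truth_multimorbid, predicted_multimorbid,
                             mmapp_time_s = NA_real_,
                             comparator_time_s = NA_real_) {
  for (tm in c(mmapp_time_s, comparator_time_s)) {
    if (!is.na(tm) && tm < 0) {
      stop("completion times must be nonnegative", call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         scenario_id = as.character(scenario_id),
         selected = unique(as.character(selected)),
         intended = unique(as.character(intended)),
         truth_multimorbid = truth_multimorbid,
         predicted_multimorbid = predicted_multimorbid,
         mmapp_time_s = as.numeric(mmapp_time_s),
         comparator_time_s = as.numeric(comparator_time_s)),
    class = "qcs_trial"
  )
}

#' Tally selection errors for one trial
#'
#' @param trial A `qcs_trial`.
#' @return Named integer vector: `n_correct` (selected and intended),
#'   `n_incorrect` (selected but not intended), `n_missed` (intended but not
#'   selected).  Always `n_correct + n_missed == |intended|` and
#'   `n_correct + n_incorrect == |selected|`.
#' @export
classify_selection_errors <- function(trial) {
  stopifnot(inherits(trial, "qcs_trial"))
  c(n_correct = length(intersect(trial$selected, trial$intended)),
    n_incorrect = length(setdiff(trial$selected, trial$intended)),
    n_missed = length(setdiff(trial$intended, trial$selected)))
}

#' Trial-level confusion counts
#'
#' Pools trials from all scenarios into one 2x2 table of true/predicted
#' multimorbidity labels.  The unit of analysis is the trial (participant x
#' scenario), matching denominators of 30 multimorbid and 20 non-multimorbid
#' trials in a 10-participant, 5-scenario design with 3 multimorbid
#' scenarios.
#'
#' @param trials List of `qcs_trial` records.
#' @return A `qcs_confusion` named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(trials) {
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (is.na(tr$truth_multimorbid) || is.na(tr$predicted_multimorbid)) {
      stop("trial ", i, " (participant ", tr$participant_id, ", scenario ",
           tr$scenario_id, "): missing truth or predicted label",
           call. = FALSE)
    }
    cell <- if (tr$truth_multimorbid) {
      if (tr$predicted_multimorbid) "tp" else "fn"
    } else {
      if (tr$predicted_multimorbid) "fp" else "tn"
    }
    counts[cell] <- counts[cell] + 1L
  }
  structure(counts, class = "qcs_confusion")
}

#' Sensitivity and specificity (percent)
#'
#' `sensitivity` = 100 * tp / (tp + fn) over truly multimorbid trials;
#' `specificity` = 100 * tn / (tn + fp) over truly non-multimorbid trials.
#' A zero denominator is an undefined metric and raises an error rather
#' than returning 0.
#'
#' @param counts A `qcs_confusion` from [confusion_counts()].
#' @return Percentage in \[0, 100\] (full precision; round for display).
#' @export
sensitivity <- function(counts) {
  if ((counts[["tp"]] + counts[["fn"]]) == 0L) {
    stop("sensitivity undefined: no truly multimorbid trials",
         call. = FALSE)
  }
  100 * counts[["tp"]] / (counts[["tp"]] + counts[["fn"]])
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  if ((counts[["tn"]] + counts[["fp"]]) == 0L) {
    stop("specificity undefined: no truly non-multimorbid trials",
         call. = FALSE)
  }
  100 * counts[["tn"]] / (counts[["tn"]] + counts[["fp"]])
}

#' Paired t test on completion times
#'
#' Classic paired t test on the differences `a - b`, with `df = n - 1` and a
#' two-sided p value from the t distribution.  Implemented directly from
#' the textbook formula (the test suite cross-checks it against
#' `stats::t.test`).
#'
#' @param a,b Equal-length numeric vectors (n >= 2), paired by participant.
#' @return List with `t`, `df`, `p`, `mean_diff` and `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("times contain missing values",
                                 call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("degenerate test: differences have zero variance", call. = FALSE)
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1L
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       mean_diff = mean(d), n = n)
}

#' Default Likert interpretation bands
#'
#' Maps a mean 1-5 agreement rating to a verbal interpretation.  Bands are
#' half-open on the left except the first; they are deliberately not
#' symmetric around the scale anchors — the published interpretation column
#' this banding reproduces labels a 4.7 mean "strongly agree" while 1.7 maps
#' to "disagree to strongly disagree" — and are configurable precisely
#' because any such banding is an editorial choice, not a statistic.
#'
#' @return Data frame with columns `lo`, `hi`, `label`; bands cover
#'   \[1, 5\] without gaps.
#' @export
default_likert_bands <- function() {
  data.frame(
    lo = c(1, 1.25, 1.75, 2.25, 2.75, 3.25, 3.75, 4.25, 4.6),
    hi = c(1.25, 1.75, 2.25, 2.75, 3.25, 3.75, 4.25, 4.6, 5),
    label = c("Strongly disagree", "Disagree to strongly disagree",
              "Disagree", "Disagree to neutral", "Neutral",
              "Neutral to agree", "Agree", "Agree to strongly agree",
              "Strongly agree"),
    stringsAsFactors = FALSE
  )
}

likert_label <- function(m, bands) {
  for (i in seq_len(nrow(bands))) {
    lo_ok <- if (i == 1L) m >= bands$lo[i] else m > bands$lo[i]
    if (lo_ok && m <= bands$hi[i]) return(bands$label[i])
  }
  NA_character_
}

#' Summarise one Likert item
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of integer agreement
#' ratings on the 1 (strongly disagree) to 5 (strongly agree) scale, plus a
#' verbal interpretation drawn from the configured banding.
#'
#' @param statement The questionnaire statement text.
#' @param ratings Integer vector, each in 1-5, length >= 2.
#' @param bands Banding data frame, see [default_likert_bands()].
#' @return A `qcs_likert` list: `statement`, `ratings`, `n`, `mean`, `sd`,
#'   `interpretation`.
#' @export
likert_summary <- function(statement, ratings,
                           bands = default_likert_bands()) {
  ratings <- as.numeric(ratings)
  if (any(is.na(ratings)) || any(ratings %% 1 != 0) ||
      any(ratings < 1) || any(ratings > 5)) {
    stop("ratings must be integers in 1-5", call. = FALSE)
  }
  if (length(ratings) < 2L) {
    stop("need at least 2 ratings for a sample SD", call. = FALSE)
  }
  m <- mean(ratings)
  structure(
    list(statement = statement, ratings = as.integer(ratings),
         n = length(ratings), mean = m, sd = stats::sd(ratings),
         interpretation = likert_label(m, bands)),
    class = "qcs_likert"
  )
}

scenario_error_rows <- function(trials) {
  scen <- vapply(trials, `[[`, character(1), "scenario_id")
  out <- lapply(split(seq_along(trials), factor(scen, unique(scen))),
                function(idx) {
    errs <- t(vapply(trials[idx], classify_selection_errors,
                     c(n_correct = 0L, n_incorrect = 0L, n_missed = 0L)))
    data.frame(
      scenario_id = trials[[idx[1]]]$scenario_id,
      n_trials = length(idx),
      truth_multimorbid = trials[[idx[1]]]$truth_multimorbid,
      n_intended = length(trials[[idx[1]]]$intended),
      n_correct_status = sum(vapply(trials[idx], function(tr)
        tr$predicted_multimorbid == tr$truth_multimorbid, logical(1))),
      # cumulative tallies, matching the published table layout:
      # "incorrectly chose 1 / >1" and "missed 1 / >1 / >2" count
      # participants with at least that many errors
      incorrect_ge1 = sum(errs[, "n_incorrect"] >= 1L),
      incorrect_gt1 = sum(errs[, "n_incorrect"] > 1L),
      missed_ge1 = sum(errs[, "n_missed"] >= 1L),
      missed_gt1 = sum(errs[, "n_missed"] > 1L),
      missed_gt2 = sum(errs[, "n_missed"] > 2L),
      total_incorrect = sum(errs[, "n_incorrect"]),
      total_missed = sum(errs[, "n_missed"]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

scenario_timing_rows <- function(trials) {
  scen <- vapply(trials, `[[`, character(1), "scenario_id")
  rows <- lapply(split(seq_along(trials), factor(scen, unique(scen))),
                 function(idx) {
    a <- vapply(trials[idx], `[[`, numeric(1), "mmapp_time_s")
    b <- vapply(trials[idx], `[[`, numeric(1), "comparator_time_s")
    row <- data.frame(scenario_id = trials[[idx[1]]]$scenario_id,
                      mean_mmapp_s = NA_real_, mean_comparator_s = NA_real_,
                      t = NA_real_, df = NA_integer_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (!anyNA(a)) row$mean_mmapp_s <- mean(a)
    if (!anyNA(b)) row$mean_comparator_s <- mean(b)
    if (!anyNA(a) && !anyNA(b) && length(a) >= 2 && stats::sd(a - b) > 0) {
      tt <- paired_t_test(a, b)
      row$t <- tt$t
      row$df <- tt$df
      row$p <- tt$p
    }
    row
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  rows
}

#' Evaluate a feasibility study
#'
#' Assembles the full study report from a trial log and an optional survey:
#' pooled confusion counts with sensitivity/specificity and overall correct
#' identification, per-scenario selection-error tallies (cumulative rows, as
#' in the published selections table), per-scenario mean completion times
#' with paired t tests where both time columns are complete, and a Likert
#' summary table.
#'
#' @param trials Non-empty list of `qcs_trial` records.
#' @param surveys Optional data frame with columns `statement` (or
#'   `statement_id`) and `rating`; one row per participant x statement.
#' @param likert_bands Banding for the Likert interpretation labels.
#' @return A `qcs_study_report` list with elements `n_trials`, `confusion`,
#'   `sensitivity_pct`, `specificity_pct`, `overall_correct` (n and pct),
#'   `scenarios` (error-tally data frame), `trials_with_incorrect` (n, pct),
#'   `trials_with_missed` (n, pct), `timing` (data frame) and `likert`
#'   (data frame or `NULL`).
#' @export
evaluate_study <- function(trials, surveys = NULL,
                           likert_bands = default_likert_bands()) {
  if (!length(trials)) stop("nothing to evaluate: empty trial list",
                            call. = FALSE)
  counts <- confusion_counts(trials)
  scen <- scenario_error_rows(trials)
  n <- length(trials)
  n_correct_status <- sum(scen$n_correct_status)

  likert <- NULL
  if (!is.null(surveys)) {
    stmt_col <- intersect(c("statement", "statement_id"), names(surveys))[1]
    if (is.na(stmt_col) || is.null(surveys$rating)) {
      stop("surveys need a 'statement'/'statement_id' and a 'rating' column",
           call. = FALSE)
    }
    likert <- do.call(rbind, lapply(
      split(surveys, factor(surveys[[stmt_col]],
                            unique(surveys[[stmt_col]]))),
      function(block) {
        ls <- likert_summary(block[[stmt_col]][1], block$rating,
                             likert_bands)
        data.frame(statement = ls$statement, n = ls$n, mean = ls$mean,
                   sd = ls$sd, interpretation = ls$interpretation,
                   stringsAsFactors = FALSE)
      }))
    rownames(likert) <- NULL
  }

  structure(
    list(n_trials = n,
         confusion = counts,
         sensitivity_pct = sensitivity(counts),
         specificity_pct = specificity(counts),
         overall_correct = list(n = n_correct_status,
                                pct = 100 * n_correct_status / n),
         scenarios = scen,
         trials_with_incorrect = list(n = sum(scen$incorrect_ge1),
                                      pct = 100 * sum(scen$incorrect_ge1) / n),
         trials_with_missed = list(n = sum(scen$missed_ge1),
                                   pct = 100 * sum(scen$missed_ge1) / n),
         timing = scenario_timing_rows(trials),
         likert = likert),
    class = "qcs_study_report"
  )
}

#' @export
print.qcs_study_report <- function(x, ...) {
  cat("<qcs_study_report> ", x$n_trials, " trials\n", sep = "")
  cat(sprintf("  sensitivity %.1f%% (%d/%d)   specificity %.1f%% (%d/%d)\n",
              x$sensitivity_pct, x$confusion[["tp"]],
              x$confusion[["tp"]] + x$confusion[["fn"]],
              x$specificity_pct, x$confusion[["tn"]],
              x$confusion[["tn"]] + x$confusion[["fp"]]))
  cat(sprintf("  correct status %d/%d (%.0f%%)   trials with an incorrect selection %d (%.0f%%)\n",
              x$overall_correct$n, x$n_trials, x$overall_correct$pct,
              x$trials_with_incorrect$n, x$trials_with_incorrect$pct))
  invisible(x)
}

#' Read / write an evaluation-ready trials CSV
#'
#' Columns: `participant_id, scenario_id, selected_ids, intended_ids,
#' predicted, truth, mmapp_time_s, comparator_time_s`, with the id lists
#' semicolon-delimited and the labels coded 0/1.  When `intended_ids` is
#' absent, scenario ids matching the bundled fixtures (A-E) fall back to
#' [builtin_scenarios()] ground truth.
#'
#' @param path CSV file path.
#' @return `read_trials_csv`: a list of `qcs_trial` records.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       scenario_id = "character"))
  needed <- c("participant_id", "scenario_id", "selected_ids",
              "predicted", "truth")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trials CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fixtures <- builtin_scenarios()
  names(fixtures) <- vapply(fixtures, `[[`, character(1), "scenario_id")
  split_ids <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";")[[1]]
  }
  lapply(seq_len(nrow(df)), function(i) {
    intended <- if ("intended_ids" %in% names(df)) {
      split_ids(df$intended_ids[i])
    } else if (df$scenario_id[i] %in% names(fixtures)) {
      fixtures[[df$scenario_id[i]]]$intended
    } else {
      stop("row ", i, ": no intended_ids column and scenario '",
           df$scenario_id[i], "' is not a bundled fixture", call. = FALSE)
    }
    new_trial_record(
      participant_id = df$participant_id[i],
      scenario_id = df$scenario_id[i],
      selected = split_ids(df$selected_ids[i]),
      intended = intended,
      truth_multimorbid = as.logical(as.integer(df$truth[i])),
      predicted_multimorbid = as.logical(as.integer(df$predicted[i])),
      mmapp_time_s = if ("mmapp_time_s" %in% names(df))
        df$mmapp_time_s[i] else NA_real_,
      comparator_time_s = if ("comparator_time_s" %in% names(df))
        df$comparator_time_s[i] else NA_real_)
  })
}

#' @rdname read_trials_csv
#' @param trials List of `qcs_trial` records to write.
#' @export
write_trials_csv <- function(trials, path) {
  df <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id,
               scenario_id = tr$scenario_id,
               selected_ids = paste(tr$selected, collapse = ";"),
               intended_ids = paste(tr$intended, collapse = ";"),
               predicted = as.integer(tr$predicted_multimorbid),
               truth = as.integer(tr$truth_multimorbid),
               mmapp_time_s = tr$mmapp_time_s,
               comparator_time_s = tr$comparator_time_s,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
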