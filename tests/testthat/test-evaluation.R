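mk_trial <- function(selected, intended, truth = TRUE, pred = truth,
                     pid = "p", sid = "S", a = NA_real_, b = NA_real_) {
  new_trial_record(pid, sid, selected, intended, truth, pred,
                   mmapp_time_s = a, comparator_time_s = b)
}

test_that("classify_selection_errors partitions selections and intent", {
  cases <- list(
    # selected, intended, expected (correct, incorrect, missed)
    list(c("x", "y"), c("x", "y"), c(2L, 0L, 0L)),
    list(c("cardiac_arrhythmia", "c2", "endocrine_metabolic_disorder"),
         c("cardiac_arrhythmia", "c2"), c(2L, 1L, 0L)),
    list(c("depression", "chronic_lung_disease", "c4"),
         c("protein_calorie_malnutrition", "depression",
           "chronic_lung_disease", "c4"), c(3L, 0L, 1L)),
    list(character(), c("x"), c(0L, 0L, 1L)),
    list(c("x"), character(), c(0L, 1L, 0L))
  )
  for (cs in cases) {
    tr <- mk_trial(cs[[1]], cs[[2]])
    err <- classify_selection_errors(tr)
    expect_identical(unname(err), cs[[3]])
    # conservation laws
    expect_identical(err[["n_correct"]] + err[["n_missed"]],
                     length(tr$intended))
    expect_identical(err[["n_correct"]] + err[["n_incorrect"]],
                     length(tr$selected))
  }
})

test_that("confusion_counts pools trial-level labels", {
  expect_identical(unname(unclass(confusion_counts(list()))),
                   c(0L, 0L, 0L, 0L))
  one <- confusion_counts(list(mk_trial("x", "x", TRUE, TRUE)))
  expect_identical(one[["tp"]], 1L)

  bad <- mk_trial("x", "x", TRUE, TRUE)
  bad$predicted_multimorbid <- NA
  expect_error(confusion_counts(list(bad)), "missing truth or predicted")

  # invariant under reordering
  set.seed(8)
  trials <- lapply(1:30, function(i)
    mk_trial("x", "x", truth = runif(1) < 0.5, pred = runif(1) < 0.5))
  c1 <- confusion_counts(trials)
  c2 <- confusion_counts(trials[sample(30)])
  expect_identical(c1, c2)
  expect_identical(sum(unclass(c1)), 30L)
})

test_that("sensitivity and specificity handle bounds and zero denominators", {
  counts <- structure(c(tp = 29L, fp = 1L, tn = 19L, fn = 1L),
                      class = "qcs_confusion")
  expect_equal(round(sensitivity(counts), 1), 96.7)
  expect_equal(specificity(counts), 95.0)
  expect_equal(
    sensitivity(structure(c(tp = 10L, fp = 0L, tn = 0L, fn = 10L),
                          class = "qcs_confusion")), 50.0)
  no_pos <- structure(c(tp = 0L, fp = 2L, tn = 3L, fn = 0L),
                      class = "qcs_confusion")
  expect_error(sensitivity(no_pos), "undefined")
  no_neg <- structure(c(tp = 5L, fp = 0L, tn = 0L, fn = 1L),
                      class = "qcs_confusion")
  expect_error(specificity(no_neg), "undefined")
})

test_that("paired_t_test matches stats::t.test and textbook edge cases", {
  expect_equal(paired_t_test(c(1, 2, 3), c(3, 2, 1))$t, 0)
  expect_equal(paired_t_test(c(1, 2, 3), c(3, 2, 1))$p, 1)

  a <- c(10, 12, 14, 16)
  b <- c(9, 11, 12, 15)
  ours <- paired_t_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)  # independent oracle
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value)

  expect_error(paired_t_test(c(5, 5), c(5, 5)), "degenerate")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least 2")

  # antisymmetry, on random draws
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(6, 50, 10)
    y <- rnorm(6, 55, 10)
    f <- paired_t_test(x, y)
    r <- paired_t_test(y, x)
    expect_equal(f$t, -r$t)
    expect_equal(f$p, r$p)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(f$t, unname(ref$statistic))
    expect_equal(f$p, ref$p.value)
  }
})

test_that("likert_summary computes mean, sample SD and banded label", {
  easy <- likert_summary("It was easy to use", c(rep(5, 8), 4, 4))
  expect_equal(easy$mean, 4.8)
  expect_equal(round(easy$sd, 2), 0.42)
  expect_identical(easy$interpretation, "Strongly agree")

  flat <- likert_summary("s", rep(3, 10))
  expect_equal(flat$mean, 3)
  expect_equal(flat$sd, 0)
  expect_identical(flat$interpretation, "Neutral")

  # two-pass formula oracle for the sample SD
  set.seed(4)
  for (i in 1:10) {
    r <- sample(1:5, 8, replace = TRUE)
    m <- sum(r) / length(r)
    sd_oracle <- sqrt(sum((r - m)^2) / (length(r) - 1))
    expect_equal(likert_summary("s", r)$sd, sd_oracle)
  }

  expect_error(likert_summary("s", c(1, 6)), "1-5")
  expect_error(likert_summary("s", c(2.5, 3)), "1-5")
  expect_error(likert_summary("s", 3L), "at least 2")
})

test_that("default banding reproduces the published interpretation column", {
  pub <- list(list(4.8, "Strongly agree"), list(4.7, "Strongly agree"),
              list(4.5, "Agree to strongly agree"),
              list(3.6, "Neutral to agree"), list(1.9, "Disagree"),
              list(1.7, "Disagree to strongly disagree"),
              list(1.6, "Disagree to strongly disagree"),
              list(1.5, "Disagree to strongly disagree"))
  bands <- default_likert_bands()
  for (cs in pub) {
    expect_identical(qcscreen:::likert_label(cs[[1]], bands), cs[[2]])
  }
})

test_that("evaluate_study assembles confusion, tallies, timing and likert", {
  expect_error(evaluate_study(list()), "empty trial list")

  trials <- list(
    mk_trial("x", "x", TRUE, TRUE, pid = "p1", sid = "S1", a = 10, b = 9),
    mk_trial("x", "x", TRUE, TRUE, pid = "p2", sid = "S1", a = 12, b = 11),
    mk_trial("x", "x", TRUE, TRUE, pid = "p3", sid = "S1", a = 14, b = 12),
    mk_trial("x", "x", TRUE, TRUE, pid = "p4", sid = "S1", a = 16, b = 15),
    mk_trial(character(), "x", FALSE, FALSE, pid = "p1", sid = "S2"),
    mk_trial("y", "x", FALSE, FALSE, pid = "p2", sid = "S2")
  )
  surveys <- data.frame(statement = rep(c("s1", "s2"), each = 4),
                        rating = c(5, 5, 4, 5, 2, 1, 2, 2))
  rep <- evaluate_study(trials, surveys)
  expect_identical(rep$n_trials, 6L)
  expect_equal(rep$sensitivity_pct, 100)
  expect_equal(rep$specificity_pct, 100)
  # timing means are hand means of the fixture times
  s1 <- rep$timing[rep$timing$scenario_id == "S1", ]
  expect_equal(s1$mean_mmapp_s, mean(c(10, 12, 14, 16)))
  expect_equal(s1$mean_comparator_s, mean(c(9, 11, 12, 15)))
  expect_equal(s1$t, paired_t_test(c(10, 12, 14, 16), c(9, 11, 12, 15))$t)
  expect_true(is.na(rep$timing$t[rep$timing$scenario_id == "S2"]))
  expect_identical(nrow(rep$likert), 2L)
  expect_equal(rep$likert$mean, c(4.75, 1.75))
  # one S2 trial has an incorrect selection
  expect_identical(rep$trials_with_incorrect$n, 1L)
})

test_that("trials CSV round-trips and falls back to fixture ground truth", {
  trials <- builtin_trial_log()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(trials, path)
  back <- read_trials_csv(path)
  expect_length(back, 50)
  for (i in c(1, 12, 50)) {
    expect_identical(back[[i]]$selected, trials[[i]]$selected)
    expect_identical(back[[i]]$intended, trials[[i]]$intended)
    expect_identical(back[[i]]$predicted_multimorbid,
                     trials[[i]]$predicted_multimorbid)
  }
  # drop intended_ids: bundled scenario ids supply ground truth
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$intended_ids <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- read_trials_csv(path2)
  expect_identical(back2[[1]]$intended, trials[[1]]$intended)
  # identical study report either way
  expect_equal(evaluate_study(back2)$confusion,
               evaluate_study(trials)$confusion)
})
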