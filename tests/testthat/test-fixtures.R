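test_that("builtin scenarios carry the printed characteristics", {
  scen <- builtin_scenarios()
  expect_length(scen, 5)
  expect_identical(vapply(scen, `[[`, character(1), "scenario_id"),
                   c("A", "B", "C", "D", "E"))
  expect_identical(vapply(scen, `[[`, logical(1), "truth_multimorbid"),
                   c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(vapply(scen, function(s) length(s$intended), integer(1)),
                   c(2L, 4L, 3L, 2L, 2L))
  expect_identical(sum(vapply(scen, function(s) length(s$intended),
                              integer(1))), 13L)
  expect_identical(vapply(scen, `[[`, integer(1), "n_total_possible"),
                   c(2L, 5L, 4L, 2L, 4L))
  expect_true(all(vapply(scen, function(s)
    s$n_total_possible >= length(s$intended), logical(1))))
  # narrative-named conditions present where the publication names them
  expect_true("cardiac_arrhythmia" %in% scen[[1]]$intended)
  expect_true(all(c("protein_calorie_malnutrition", "depression",
                    "chronic_lung_disease") %in% scen[[2]]$intended))
  expect_true("acute_kidney_injury" %in% scen[[3]]$intended)
  expect_true(all(c("pneumonia", "substance_abuse") %in% scen[[5]]$intended))
})

test_that("toy catalog reproduces every scenario truth label", {
  cat <- builtin_toy_catalog()
  expect_true(cat$non_clinical)
  expect_identical(nrow(validate_catalog(cat)), 0L)
  for (fx in builtin_scenarios()) {
    expect_identical(evaluate_profile(fx$intended, cat)$is_multimorbid,
                     fx$truth_multimorbid, label = fx$scenario_id)
  }
  # E stays multimorbid without pneumonia (redundant qualifying sets)
  e <- builtin_scenarios()[[5]]
  expect_true(evaluate_profile(setdiff(e$intended, "pneumonia"),
                               cat)$is_multimorbid)
})

test_that("generate_patient draws independent Bernoulli per condition", {
  cat <- builtin_toy_catalog()
  expect_identical(generate_patient(cat, prevalence = 0, seed = 1),
                   character())
  expect_identical(generate_patient(cat, prevalence = 1, seed = 1),
                   names(cat$conditions))
  expect_identical(generate_patient(cat, 0.3, seed = 42),
                   generate_patient(cat, 0.3, seed = 42))
  expect_error(generate_patient(cat, prevalence = 1.2), "\\[0, 1\\]")
  expect_error(generate_patient(cat, prevalence = c(ghost = 0.5)),
               "not in catalog")

  named <- generate_patient(
    cat, prevalence = c(pneumonia = 1, depression = 1), seed = 2)
  expect_setequal(named, c("pneumonia", "depression"))

  # emitted codes map back to the conditions that produced them
  out <- generate_patient(cat, prevalence = 0.6, seed = 9,
                          emit_codes = TRUE)
  if (nrow(out$diagnoses)) {
    mapped <- map_record(out$diagnoses, cat)
    expect_true(all(mapped$profile %in% out$profile))
  }
})

test_that("simulate_trials is seeded, sized, and error-free at zero rates", {
  cat <- builtin_toy_catalog()
  perfect <- simulate_trials(rater = new_rater_model(0, 0),
                             n_participants = 10, catalog = cat, seed = 1)
  expect_length(perfect, 50)
  for (tr in perfect) {
    expect_setequal(tr$selected, tr$intended)
    expect_identical(tr$predicted_multimorbid, tr$truth_multimorbid)
  }
  rep <- evaluate_study(perfect)
  expect_equal(rep$sensitivity_pct, 100)
  expect_equal(rep$specificity_pct, 100)

  t1 <- simulate_trials(seed = 7, catalog = cat)
  t2 <- simulate_trials(seed = 7, catalog = cat)
  expect_identical(lapply(t1, unclass), lapply(t2, unclass))

  # with false_select_rate = 0, no incorrect selections; with miss_rate = 0,
  # no misses
  no_false <- simulate_trials(rater = new_rater_model(0.5, 0),
                              catalog = cat, seed = 3)
  for (tr in no_false) {
    expect_identical(classify_selection_errors(tr)[["n_incorrect"]], 0L)
  }
  no_miss <- simulate_trials(rater = new_rater_model(0, 0.3),
                             catalog = cat, seed = 3)
  for (tr in no_miss) {
    expect_identical(classify_selection_errors(tr)[["n_missed"]], 0L)
  }
  expect_error(new_rater_model(-0.1, 0), "\\[0, 1\\]")
})

test_that("builtin trial log reproduces the published per-scenario tallies", {
  trials <- builtin_trial_log()
  expect_length(trials, 50)
  rep <- evaluate_study(trials)
  scen <- rep$scenarios
  expect_identical(scen$n_correct_status, c(9L, 9L, 10L, 10L, 10L))
  expect_identical(scen$incorrect_ge1, c(2L, 1L, 0L, 0L, 0L))
  expect_identical(scen$incorrect_gt1, rep(0L, 5))
  expect_identical(scen$missed_ge1, c(2L, 9L, 3L, 0L, 6L))
  expect_identical(scen$missed_gt1, c(0L, 3L, 0L, 0L, 3L))
  expect_identical(scen$missed_gt2, rep(0L, 5))

  # narrative details: who missed / wrongly chose what
  a_extra <- unlist(lapply(trials[1:10], function(tr)
    setdiff(tr$selected, tr$intended)))
  expect_setequal(a_extra, c("endocrine_metabolic_disorder",
                             "acute_kidney_injury"))
  b_missed <- unlist(lapply(trials[11:20], function(tr)
    setdiff(tr$intended, tr$selected)))
  expect_identical(sum(b_missed == "protein_calorie_malnutrition"), 9L)
  expect_identical(sum(b_missed == "depression"), 3L)
  e_missed <- unlist(lapply(trials[41:50], function(tr)
    setdiff(tr$intended, tr$selected)))
  expect_identical(sum(e_missed == "pneumonia"), 6L)
  expect_identical(sum(e_missed == "substance_abuse"), 3L)
})
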