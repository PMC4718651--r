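# Scenario grouping, choice aggregates, authority contrasts, and the
# observed-versus-predicted judgment comparison.

test_that("classification reproduces the published group structure", {
  cls2 <- classify_scenarios(study2_designs())
  # 13 + 10 + 7 + 10 scenarios by posterior level
  expect_equal(unname(table(cls2$level)[as.character(c(0.5, 0.67, 0.8, 0.89))]),
               c(10L, 13L, 10L, 7L), ignore_attr = TRUE)
  # printed section memberships
  expect_equal(cls2$authority[cls2$scenario_id %in% as.character(c(1:4, 14:16, 24, 25, 31:33))],
               rep("baseline", 12))
  expect_equal(cls2$authority[cls2$scenario_id %in% as.character(c(5, 6, 17:21, 26:30, 34, 35))],
               rep("supports", 14))
  expect_equal(cls2$authority[cls2$scenario_id %in% as.character(c(7:13, 22, 23, 36:40))],
               rep("opposes", 14))
  # spot checks: authority seconding vs contradicting the private signal
  expect_equal(cls2$authority[cls2$scenario_id == "5"], "supports")
  expect_equal(cls2$level[cls2$scenario_id == "5"], 0.67)
  expect_equal(cls2$authority[cls2$scenario_id == "36"], "opposes")
  expect_equal(cls2$level[cls2$scenario_id == "36"], 0.50)
  # peer-only designs are all baseline
  expect_true(all(classify_scenarios(study1_designs())$authority == "baseline"))
  # relation labels: cascade scenarios are exactly the private-overriding ones
  expect_setequal(cls2$scenario_id[cls2$relation == "cascade"],
                  as.character(c(3, 4, 9:13)))
})

test_that("published per-scenario proportions aggregate to the printed group means", {
  agg1 <- printed_aggregates("study1")
  expect_equal(round(agg1[["bayes_all"]], 1), 86.9)
  expect_equal(round(agg1[["bayes_private_favored"]], 1), 90.2)
  expect_equal(round(agg1[["cascade_bayes"]], 1), 75.5)
  expect_equal(round(agg1[["private_indifference"]], 1), 79.9)
  agg2 <- printed_aggregates("study2")
  expect_equal(round(agg2[["bayes_private_favored"]], 1), 95.1)
  expect_equal(round(agg2[["cascade_bayes"]], 1), 82.1)
})

test_that("choice aggregation follows the stated rule and rejects undefined requests", {
  designs <- study1_designs()
  # perfectly Bayesian records give 100% consistency on directional scenarios
  directional <- designs[as.character(1:9)]
  cls <- classify_scenarios(directional)
  rec <- do.call(rbind, lapply(1:5, function(i)
    data.frame(participant_id = paste0("p", i),
               scenario_id = cls$scenario_id, choice = cls$bayes_option)))
  agg <- aggregate_choices(rec, directional, "bayes_consistent")
  expect_true(all(agg$proportion == 1))
  expect_equal(sum(agg$n_choices), 45L)
  # bayes-consistency is undefined at the indifference level
  rec0 <- data.frame(participant_id = "p1", scenario_id = "10", choice = "A")
  expect_error(aggregate_choices(rec0, designs, "bayes_consistent"),
               "indifference")
  expect_equal(aggregate_choices(rec0, designs, "private_consistent")$proportion,
               0)  # private signal favoured B
})

test_that("authority tests: identical conditions are degenerate, not significant", {
  designs <- study2_designs()
  cls <- classify_scenarios(designs)
  # every participant always follows the private signal: conditions identical
  rec <- do.call(rbind, lapply(1:8, function(i)
    data.frame(participant_id = paste0("p", i), scenario_id = cls$scenario_id,
               choice = cls$private_option,
               judgment = 0.7)))
  at <- authority_tests(rec, designs)
  expect_true(all(at$z == 0))
  expect_true(all(at$p_choice == 1))
  expect_true(all(at$choice_flag == "degenerate"))
  expect_true(all(at$judgment_flag == "degenerate"))
  expect_error(authority_tests(rec[rec$participant_id == "p1", ], designs),
               "at least 2")
})

test_that("an authority-weighted cohort shows the directional oppose effect", {
  truth <- influence_params(beta_bias = 0, beta_HR = 1.5, beta_ER = 0.8,
                            theta = 6.08, form = "study2")
  rec <- simulate_cohort(cohort_spec(120, study2_designs(), truth, seed = 71))
  at <- authority_tests(rec, study2_designs())
  opp <- at[at$comparison == "baseline_vs_opposes" & at$level == 0.5, ]
  expect_lt(opp$p_choice, 0.01)
  # fewer private-consistent choices when the authority opposes
  expect_lt(opp$choice_condition, opp$choice_baseline)
})

test_that("judgment comparison is self-consistent for a noiseless cohort", {
  design <- study1_designs()
  rec <- simulate_bayesian_cohort(60, design, theta = 9.9, seed = 23)
  bayes <- influence_params(beta_bias = 0, beta_soc = 1, theta = 9.9)
  jc <- judgment_comparison(rec, bayes, design)
  expect_equal(nrow(jc), 4L)
  # observed judgments are generated by the same rule the model predicts
  expect_true(all(abs(jc$observed - jc$predicted) < 0.02))
  # near-deterministic choices make both approach the normative posterior
  expect_true(all(abs(jc$predicted - jc$normative) < 0.02))
})

test_that("an overweighting cohort produces the compression pattern of judgments", {
  params <- influence_params(beta_bias = 0, beta_soc = 0.78, theta = 6.08)
  rec <- simulate_cohort(cohort_spec(80, study1_designs(), params, seed = 24))
  jc <- judgment_comparison(rec, params, study1_designs())
  expect_gt(jc$predicted[jc$level == 0.5], 0.5)
  expect_lt(jc$predicted[jc$level == 0.89], 0.89)
  expect_gt(jc$observed[jc$level == 0.5], 0.5)
})

test_that("predictions never read the judgment column", {
  params <- truth_study1()
  rec <- simulate_cohort(cohort_spec(10, study1_designs(), params, seed = 25))
  blinded <- rec
  blinded$judgment <- NA_real_
  jc_full <- judgment_comparison(rec, params, study1_designs())
  jc_blind <- judgment_comparison(blinded, params, study1_designs())
  expect_equal(jc_blind$predicted, jc_full$predicted)
  expect_true(all(is.nan(jc_blind$observed) | is.na(jc_blind$observed)))
})
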