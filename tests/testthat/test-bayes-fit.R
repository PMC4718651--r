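# MCMC estimation: likelihood contract, prior recovery, pooling arithmetic,
# contrasts, HDI and convergence diagnostics.

fast_config <- function(seed = 1L)
  chain_config(n_chains = 2, kept = 600, thinning = 4, burn_in = 400,
               seed = seed)

test_that("choice log likelihood matches closed forms and is exchangeable", {
  designs <- study1_designs()
  bayes <- influence_params(beta_bias = 0, beta_soc = 1, theta = 6.08)
  # indifference scenario: any choice has probability one half
  rec <- data.frame(participant_id = "p1", scenario_id = "10", choice = "A")
  expect_equal(log_likelihood(rec, bayes, designs), log(0.5))
  # scenario 1 (posterior 0.80), choice of the favoured option
  rec1 <- data.frame(participant_id = "p1", scenario_id = "1", choice = "A")
  # fixture reliabilities are stored to 6 significant digits
  expect_equal(log_likelihood(rec1, bayes, designs),
               log(choice_probability(0.8, 0.2, 6.08)), tolerance = 1e-5)
  # trial order is irrelevant
  many <- data.frame(participant_id = "p1",
                     scenario_id = c("1", "6", "10", "3"),
                     choice = c("A", "B", "A", "A"))
  expect_equal(log_likelihood(many, bayes, designs),
               log_likelihood(many[c(3, 1, 4, 2), ], bayes, designs))
  expect_error(log_likelihood(data.frame(participant_id = "p1",
                                         scenario_id = "zz", choice = "A"),
                              bayes, designs), "unknown scenario")
})

test_that("the sampler's vectorised likelihood equals the standalone operation", {
  designs <- study2_designs()
  rec <- simulate_cohort(cohort_spec(3, designs, truth_study2(), seed = 6))
  set.seed(42)
  for (i in 1:10) {
    params <- influence_params(beta_bias = runif(1, -0.9, 0.9),
                               beta_HR = runif(1, 0.1, 1.9),
                               beta_ER = runif(1, 0.1, 1.9),
                               theta = runif(1, 0.5, 9.5), form = "study2")
    for (pid in unique(rec$participant_id)) {
      sub <- rec[rec$participant_id == pid, ]
      # independent route: per-record Bernoulli log probabilities
      by_hand <- sum(vapply(seq_len(nrow(sub)), function(j) {
        pc <- predict_scenario(designs[[sub$scenario_id[j]]], params)$choice_prob_A
        log(if (sub$choice[j] == "A") pc else 1 - pc)
      }, numeric(1)))
      expect_equal(log_likelihood(sub, params, designs), by_hand,
                   tolerance = 1e-10)
    }
  }
})

test_that("with no data the posterior reproduces the prior", {
  empty <- data.frame(participant_id = character(), scenario_id = character(),
                      choice = character())
  s <- fit_participant(empty, study1_designs(), "study1",
                       config = fast_config(31))
  # prior medians: beta_soc 1 (uniform 0-2), theta 5 (uniform 0-10),
  # beta_bias 0 (flat truncated normal)
  expect_lt(abs(s$median[["beta_soc"]] - 1), 0.25)
  expect_lt(abs(s$median[["theta"]] - 5), 0.6)
  expect_lt(abs(s$median[["beta_bias"]]), 0.25)
  expect_true(all(abs(s$samples[, "beta_bias"]) <= 1))
  expect_true(all(s$samples[, "beta_soc"] > 0 & s$samples[, "beta_soc"] < 2))
})

test_that("fitting is deterministic given the seed", {
  rec <- simulate_cohort(cohort_spec(3, study1_designs(), truth_study1(),
                                     seed = 4))
  f1 <- fit_cohort(rec, study1_designs(), "study1", config = fast_config(9))
  f2 <- fit_cohort(rec, study1_designs(), "study1", config = fast_config(9))
  expect_identical(f1$summaries[[1]]$samples, f2$summaries[[1]]$samples)
  expect_identical(vapply(f1$summaries, function(s) s$median["beta_soc"],
                          numeric(1)),
                   vapply(f2$summaries, function(s) s$median["beta_soc"],
                          numeric(1)))
})

test_that("a Bayesian cohort's pooled social-weight HDI covers unity", {
  design <- study1_mirrored()
  rec <- simulate_bayesian_cohort(20, c(design, design), theta = 6.08,
                                  seed = 16)
  fit <- fit_cohort(rec, design, "study1", config = fast_config(17))
  pooled <- pool_group(fit)
  expect_lte(pooled$hdi_lower[["beta_soc"]], 1)
  expect_gte(pooled$hdi_upper[["beta_soc"]], 1)
  expect_lt(abs(pooled$median[["beta_bias"]]), 0.15)
})

test_that("pooling: identity for one participant, arithmetic for point masses, order invariance", {
  a <- point_mass_summary(c(beta_soc = 0.6, theta = 4))
  b <- point_mass_summary(c(beta_soc = 1.0, theta = 6))
  pooled <- pool_group(list(a, b))
  expect_equal(unname(pooled$median), c(0.8, 5))
  expect_equal(unname(pooled$hdi_upper - pooled$hdi_lower), c(0, 0))
  # single input is the identity
  solo <- pool_group(list(a))
  expect_equal(solo$median, a$median)
  expect_equal(solo$samples, a$samples)
  # permutation invariance
  rec <- simulate_cohort(cohort_spec(4, study1_designs(), truth_study1(),
                                     seed = 19))
  fit <- fit_cohort(rec, study1_designs(), "study1", config = fast_config(20))
  p1 <- pool_group(fit$summaries)
  p2 <- pool_group(rev(fit$summaries))
  expect_equal(p1$median, p2$median)
  expect_equal(p1$samples, p2$samples)
  expect_error(pool_group(list()), "at least one")
})

test_that("chains of unequal length are thinned to a common length before pooling", {
  a <- point_mass_summary(c(beta_soc = 0.5), n = 200L)
  b <- point_mass_summary(c(beta_soc = 1.5), n = 300L)
  pooled <- pool_group(list(a, b))
  expect_equal(nrow(pooled$samples), 200L)
  expect_equal(unname(pooled$median), 1.0)
})

test_that("contrasts are sample-wise arithmetic on the chains", {
  at_bayes <- point_mass_summary(c(beta_soc = 1))
  expect_equal(unname(contrast(at_bayes, "private_minus_public_s1")$median), 0)
  s2 <- point_mass_summary(c(beta_HR = 1.12, beta_ER = 0.85))
  expect_equal(unname(contrast(s2, "HR_minus_ER")$median), 0.27)
  expect_equal(unname(contrast(s2, "private_weight")$median), 1.03)
  # private weight 1.03 versus the peer weight 0.85
  expect_equal(unname(contrast(s2, "private_minus_ER")$median), 0.18)
  expect_equal(unname(contrast(s2, "private_minus_HR")$median), -0.09)
  expect_error(contrast(at_bayes, "HR_minus_ER"), "wrong model form")
})

test_that("HDI: analytic widths, point masses, and the sample-size guard", {
  set.seed(2)
  u <- runif(20000)
  h <- hdi(u, 0.95)
  expect_lt(abs((h[2] - h[1]) - 0.95), 0.01)
  z <- rnorm(50000)
  hz <- hdi(z, 0.95)
  expect_lt(abs(hz[1] + 1.96), 0.05)
  expect_lt(abs(hz[2] - 1.96), 0.05)
  p <- hdi(rep(3.3, 500))
  expect_equal(unname(p[2] - p[1]), 0)
  expect_error(hdi(rnorm(50)), "at least 100")
})

test_that("split-R-hat separates mixed from unmixed chains", {
  set.seed(3)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  bad <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(split_rhat(bad), 1.5)
  # constant chains are not flagged
  expect_equal(split_rhat(matrix(1, 100, 2)), 1)
})

test_that("degenerate configurations and inputs are refused", {
  expect_error(chain_config(kept = 0), "empty")
  expect_error(chain_config(thinning = 0), "positive")
  rec <- simulate_cohort(cohort_spec(2, study1_designs(), truth_study1(),
                                     seed = 5))
  expect_error(fit_participant(rec, study1_designs(), "study1"),
               "exactly one participant")
  expect_error(fit_cohort(data.frame(participant_id = "p1",
                                     scenario_id = "zz", choice = "A"),
                          study1_designs(), "study1"), "unknown scenario")
})
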