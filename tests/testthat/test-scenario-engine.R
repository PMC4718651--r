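# Signal inference from public decisions, normative Bayesian posteriors, and
# scenario validation.

test_that("the three-decider worked example reproduces its inference and log odds", {
  # two predecessors choose A, focal actor draws b: both decisions are
  # informative, so two a-signals and one b-signal
  s <- scenario("worked", c("A", "A"), private_signal = "b")
  ledger <- infer_public_signals(s)
  expect_equal(ledger$public$signal, c("a", "a"))
  expect_equal(ledger$private, "b")
  expect_equal(ledger$n_a, 2)
  expect_equal(ledger$n_b, 1)
  expect_equal(round(log_odds(ledger), 2), 0.69)
  # positive log odds: A should be selected despite the private b-signal
  expect_gt(log_odds(ledger), 0)
})

test_that("informative decisions reveal signals; cascade decisions reveal nothing", {
  # third A-decision after two a-signals is uninformative
  s3 <- scenario("cascade", c("A", "A", "A"), private_signal = "b")
  ledger <- infer_public_signals(s3)
  expect_equal(nrow(ledger$public), 2L)
  # posterior identical to the two-predecessor case
  s2 <- scenario("short", c("A", "A"), private_signal = "b")
  expect_equal(scenario_posterior(s3), scenario_posterior(s2))
  # a decision at a restored tie (A, B, then A) is informative again
  tie <- infer_public_signals(scenario("tie", c("A", "B", "A"),
                                       private_signal = "a"))
  expect_equal(tie$public$signal, c("a", "b", "a"))
  # empty history: only the private signal
  none <- infer_public_signals(scenario("none", character(),
                                        private_signal = "a"))
  expect_equal(nrow(none$public), 0L)
  expect_equal(none$n_a, 1)
  # inferred signals carry their source's rank
  ranked <- infer_public_signals(scenario("rk", c("A", "B"), c("HR", "EQ"),
                                          private_signal = "a"))
  expect_equal(ranked$public$rank, c("HR", "EQ"))
})

test_that("never more public signals than predecessors; counts always consistent", {
  set.seed(404)
  for (i in 1:60) {
    n <- sample(0:3, 1)
    preds <- sample(c("A", "B"), n, replace = TRUE)
    s <- scenario(paste0("r", i), preds, private_signal = sample(c("a", "b"), 1))
    if (!validate_scenario(s)$valid) next
    ledger <- infer_public_signals(s)
    expect_lte(nrow(ledger$public), length(preds))
    expect_equal(ledger$n_a + ledger$n_b,
                 nrow(ledger$public) + length(ledger$private))
  }
})

test_that("unreasonable decisions (against a settled margin) are rejected with the index", {
  v <- validate_scenario(scenario("bad", c("A", "A", "B"), private_signal = "a"))
  expect_false(v$valid)
  expect_match(v$reason, "predecessor 3")
  expect_true(validate_scenario(scenario("ab", c("A", "B"),
                                         private_signal = "a"))$valid)
  expect_true(validate_scenario(scenario("empty", character(),
                                         private_signal = "b"))$valid)
  expect_error(infer_public_signals(scenario("bad", c("A", "A", "B"),
                                             private_signal = "a")),
               "predecessor 3")
})

test_that("log-odds pipeline matches brute-force Bayes on all small ledgers", {
  # exhaustive: every (public a/b, private a/b) count split with <= 5 signals,
  # three reliability settings
  for (p in c(0.6, 2 / 3, 0.75)) {
    spec <- likelihood_spec(p)
    for (pa in 0:5) for (pb in 0:(5 - pa))
      for (va in 0:(5 - pa - pb)) for (vb in 0:(5 - pa - pb - va)) {
        ledger <- signal_ledger(public = rep(c("a", "b"), c(pa, pb)),
                                private = rep(c("a", "b"), c(va, vb)))
        expect_equal(posterior_from_log_odds(log_odds(ledger, spec)),
                     bayes_posterior_bruteforce(ledger, spec),
                     tolerance = 1e-12)
      }
  }
})

test_that("posterior depends only on the signal difference under symmetric reliabilities", {
  spec <- likelihood_spec(2 / 3)
  expect_equal(log_odds(signal_ledger(private = c("a", "a", "b")), spec),
               log_odds(signal_ledger(private = "a"), spec))
  expect_equal(log_odds(signal_ledger(public = rep("a", 3),
                                      private = rep("b", 3)), spec), 0)
  # n_a = 3, n_b = 1 gives twice the single-signal log odds
  expect_equal(log_odds(signal_ledger(public = c("a", "a", "a"),
                                      private = "b"), spec),
               2 * log(2), tolerance = 1e-12)
})

test_that("posterior transform behaves: fixed points, symmetry, monotonicity", {
  expect_equal(posterior_from_log_odds(0), 0.5)
  expect_equal(round(posterior_from_log_odds(log(2)), 2), 0.67)
  expect_equal(round(posterior_from_log_odds(2 * log(2)), 2), 0.80)
  l <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(posterior_from_log_odds(l)) > 0))
  expect_equal(posterior_from_log_odds(l) + posterior_from_log_odds(-l),
               rep(1, length(l)))
  # prior enters the brute-force form: empty ledger returns the prior
  expect_equal(bayes_posterior_bruteforce(signal_ledger(),
                                          likelihood_spec(2 / 3, 0.3)), 0.3)
  expect_equal(bayes_posterior_bruteforce(signal_ledger(private = "a")), 2 / 3)
})

test_that("mirroring is an involution and flips the posterior", {
  for (s in c(study1_designs(), study2_designs())) {
    m <- mirror_scenario(s)
    back <- mirror_scenario(m)
    expect_equal(back$predecessors, s$predecessors)
    expect_equal(back$private_signal, s$private_signal)
    expect_equal(back$scenario_id, s$scenario_id)
    expect_equal(scenario_posterior(m), 1 - scenario_posterior(s),
                 tolerance = 1e-12)
    # ranks are untouched by mirroring
    expect_equal(m$ranks, s$ranks)
  }
  m <- mirror_scenario(scenario("x", c("A", "A"), private_signal = "b"))
  expect_equal(m$predecessors, c("B", "B"))
  expect_equal(m$private_signal, "a")
})

test_that("degenerate likelihood specs are refused", {
  expect_error(likelihood_spec(0.5), "informative")
  expect_error(likelihood_spec(1), "between 0 and 1")
  expect_error(likelihood_spec(2 / 3, 0), "prior_A")
  expect_error(scenario("x", c("A", "C"), private_signal = "a"))
  expect_error(scenario("x", rep("A", 4), private_signal = "a"), "at most 3")
  expect_silent(scenario("x", rep("A", 4), private_signal = "a",
                         max_predecessors = 10))
})
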