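---
title: "Modelling social influence in sequential binary decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social influence in sequential binary decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialcascade)
```

## The decision problem

A focal decision maker must choose between two states of the world, coded
`A` and `B` (two urns differing in their majority ball colour; two candidate
diagnoses). They hold one binary private signal (`a` or `b`) that matches
the true state with reliability $p = p(a \mid A) = p(b \mid B)$ — $2/3$
throughout the packaged designs — and they observe the announced decisions
of up to three predecessors who faced the same problem with their own
private signals. Predecessors' signals are never observed directly; they
must be inferred from the decisions.

### Inferring signals from decisions

`infer_public_signals()` forward-simulates the public evidence state. Let
`net` be the margin of inferred a-signals over b-signals across the
predecessors processed so far.

* **`|net| <= 1`: the decision is informative** and reveals the decider's
  private signal exactly. At `net = 0` the decider is at posterior
  indifference and follows their own signal (the tie-break assumption). At
  `net = ±1` a decider holding the opposing signal would find themselves at
  a tie and, by the same assumption, follow their own signal — so whichever
  way the decision goes, it matches the decider's signal.
* **`|net| >= 2`: the decision is uninformative.** A rational decider
  inside a cascade chooses the margin's option under either signal, so the
  decision carries no evidence and contributes no signal. A decision
  *against* such a margin cannot arise from the assumed process at all;
  `validate_scenario()` flags it ("unreasonable") and names the offending
  position, and such designs are excluded from the packaged sets.

The `|net| <= 1` informativeness threshold is the one formalisation point
the verbal task description leaves open. It is forced by two observations:
a third same-way decision must change nothing (the packaged designs print
identical posteriors for two- and three-decision cascades), while a
decision at a restored tie must be fully revealing (otherwise the
0.80-level designs with an interior disagreement would not reach their
printed posteriors). The whole inference logic lives in this one function.

### The normative posterior

Signals accumulate on the log-odds scale: with $n_a$ a-signals and $n_b$
b-signals,

$$\ln\frac{p(A \mid n_a, n_b)}{p(B \mid n_a, n_b)} =
\sum_{i=1}^{n_a} \ln\frac{p(a \mid A)}{p(a \mid B)} +
\sum_{i=1}^{n_b} \ln\frac{p(b \mid A)}{p(b \mid B)},$$

so with symmetric reliability only the difference $n_a - n_b$ matters, each
net signal contributing $\ln 2$ at $p = 2/3$. `posterior_from_log_odds()`
maps back to a probability, and `bayes_posterior_bruteforce()` evaluates
Bayes' theorem directly from likelihood products as an independent oracle
for the pipeline — the two routes agree to $10^{-12}$ over all ledgers with
up to five signals at reliabilities 0.6, $2/3$ and 0.75.

```{r}
s <- scenario("cascade", c("A", "A"), private_signal = "b")
infer_public_signals(s)
round(scenario_posterior(s), 2)
```

## The social influence model

People need not weight inferred and private evidence equally. The model
re-weights the log-likelihood-ratio sums by source:

* **Peer form** (one public source class):
  $\beta_{bias} + \beta_{soc}\sum_{public} f(x) + (2-\beta_{soc})\sum_{private} f(x)$
  with $f(x) = \ln p(x\mid A)/p(x \mid B)$. The total weight is conserved
  at 2; $\beta_{soc} = 1,\ \beta_{bias} = 0$ recovers the Bayesian solution,
  $\beta_{soc} < 1$ means private information is overweighted.
* **Rank form** (public sources split by hierarchical rank):
  $\beta_{bias} + \beta_{HR}\sum_{HR} f(x) + \beta_{ER}\sum_{ER} f(x) +
  (3-\beta_{HR}-\beta_{ER})\sum_{private} f(x)$, where `HR` tags signals
  inferred from a higher ranked source and `ER` from equally ranked peers.

Rank weights attach to *inferred signals* only: an uninformative cascade
decision contributes no signal, so it receives no weight even when made by
the authority. That is the rank form exactly as written; behavioural data
might motivate letting uninformative authority decisions carry weight, but
that would be a different model.

Choices follow a sensitivity rule on the subjective posteriors,
$p_{choose}(A) = 1/(1 + e^{\theta\,(p_B - p_A)})$ with $\theta \in (0, 10)$:
indifferent at $\theta = 0$, nearly deterministic at the upper end.

### Predicted probability judgments

Participants also judged the probability that their choice was correct, on
a half-to-one scale. The model is never fitted to these judgments; they are
predicted from the subjective posteriors, which makes the comparison a
genuine generalization test. When the model is uncertain which option will
be chosen, two mappings are defensible, and the task description does not
choose one:

* `"expected"` (default): the expectation over the model's own choice
  distribution of the subjective posterior of the chosen option,
  $p_c\,p_s + (1-p_c)(1-p_s) = \tfrac12 + 2(p_s-\tfrac12)(p_c-\tfrac12)
  \ge \tfrac12$. This matches how per-scenario averages over participants
  are formed (each participant reports the confidence of the option they
  actually chose).
* `"argmax"`: the subjective posterior of the modal option,
  $\max(p_s, 1-p_s)$. This yields slightly higher values (0.585 vs. 0.543
  at the group-median peer-form parameters on the indifference designs) and
  is closer to published point predictions, suggesting it is what the
  original figures used; it is available everywhere via the
  `judgment_rule` argument.

Either way the qualitative compression pattern is the same and is what the
tests assert: overconfidence at the normative-0.50 level, underconfidence
at the 0.89 level, both driven by $\beta_{soc} < 1$.

## Synthetic cohorts

`simulate_cohort()` makes every downstream stage testable without real
data, which was never deposited. Each synthetic participant draws
parameters from independent truncated Gaussians (or fixed values), answers
the fixed designs with Bernoulli choices from the choice rule, and reports
a judgment equal to the subjective posterior of the chosen option plus
truncated Gaussian noise on the probability scale, clamped to $[0.5, 1]$.
Defaults mirror the study conditions: 40 participants, the 24 mirrored
urn-design presentations (doubled to 48 trials for recovery runs) or the 40
clinical designs, judgment noise sd 0.05 (the task description specifies no
noise model; 0.05 is roughly the granularity of a percent-scale slider
response). Per-participant seeds are derived deterministically from one
master seed, so enlarging a cohort never reshuffles existing participants.

What the generator does *not* emulate: sequential dependencies between a
participant's own trials (order effects, learning), response biases in the
judgment scale use (rounding to multiples of 5, anchoring), and live
cascades in which participants' decisions feed each other. Passing
recovery tests therefore show that the estimation machinery is correct and
well calibrated for the assumed generative process — not that real
participants satisfy these independence assumptions.

## Estimation

Each participant is fitted separately by MCMC on the posterior
prior × Bernoulli choice likelihood. Priors follow the original estimation:
truncated normal (mean 0, sd 10, truncated at ±1, enforced by rejection)
for $\beta_{bias}$; uniform on $(0, 2)$ for each social weight; uniform on
$(0, 10)$ for $\theta$. The verbal "standard deviation of 10" for the bias
prior conflicts with the also-stated precision 0.1 (sd ≈ 3.16); sd = 10 is
used for both forms — it matches the verbal statement and the rank-form
precision 0.01 — and is configurable via `prior_spec()`. Rank-form priors
for $\beta_{HR}$ and $\beta_{ER}$ are not separately documented; each
mirrors the peer weight's uniform $(0,2)$, with the documented consequence
that the implied private weight $3-\beta_{HR}-\beta_{ER}$ can go negative
when both approach 2.

The sampler is a random-walk Metropolis scheme, vectorised across
participants and chains (participants are independent, so all chains
advance in lock-step through matrix operations). Any correct MCMC scheme
satisfies the contract; what is checked is the contract itself: the
sampler's vectorised likelihood equals the standalone `log_likelihood()`
to $10^{-10}$, and split-$\hat R$ must stay below 1.01 per participant and
parameter or the summary is flagged (never silently returned). Proposal
scales (0.15–0.2 for weights, 0.8 for $\theta$) give healthy acceptance
rates for 24–48-trial likelihoods. Subjective log odds are clipped at ±50
before exponentiation so that no admissible parameter value produces a
zero-probability choice.

`chain_config()` exposes two profiles. `"paper"` mirrors the original
settings (burn-in 10,000, thinning 100, ~50,000 kept across chains; the
original description is ambiguous about whether its "net length" counts
kept samples or raw iterations, so both knobs are exposed). `"desk"` — the
default and the profile used by every test and analysis script — keeps
5,000 samples (4 chains × 1,250, thinning 8, burn-in 1,000), which is ample
for 3–4-parameter posteriors and fits a 40-participant cohort in a few
seconds.

### Group pooling and contrasts

Group estimates average the participants' Markov chains sample-wise
(sample $i$ of the group chain is the participant mean of sample $i$), then
summarise by median and 95% HDI; this reproduces the narrow published group
intervals, whereas concatenating chains (available via
`pool_group(method = "concatenate")`) would give the much wider mixture
distribution. The HDI is the narrowest sorted-sample window containing the
target mass. `contrast()` performs sample-wise arithmetic for derived
quantities: private-minus-public weight $2-2\beta_{soc}$ in the peer form;
$\beta_{HR}-\beta_{ER}$, the private weight $3-\beta_{HR}-\beta_{ER}$, and
its differences with either public weight in the rank form.

### What recovery shows — and its limits

At study scale (40 participants, 48 or 40 trials), the pooled medians of
the social weights recover simulation truths to within a few hundredths.
Two systematic effects remain and are worth knowing about. First,
per-participant posterior medians of logistic-type models carry the classic
small-sample away-from-zero bias plus shrinkage toward the prior centre;
averaging over participants reduces variance but not these offsets (the
bias weight lands near −0.15 when the truth is −0.12; the offset shrinks
roughly as $1/n_{trials}$). Second, because the pooled group HDI narrows
as $1/\sqrt{n_{participants}}$ while those offsets do not, the group HDI's
frequentist coverage of the truth sits just below its nominal level for
the most affected parameter — about 75–80% in 20-replicate experiments.
The sensitivity parameter is the least determined: above $\theta \approx 7$
the choice probabilities saturate and the likelihood flattens, so its
posterior median shrinks noticeably toward the uniform prior's centre.

## Reporting layer

`classify_scenarios()` derives every group label from scenario content:
the posterior level (0.50/0.67/0.80/0.89), the relation between the
Bayesian prediction and the private signal (agreeing, overriding
"cascade", or indifferent), and the authority condition (baseline when no
higher ranked source is present; otherwise supporting or opposing the
option the private signal favours). `study_aggregates()` then takes
unweighted means of per-scenario proportions over these groups — exactly
the arithmetic that reproduces the published headline percentages from the
packaged per-scenario tables.

`authority_tests()` compares conditions within a posterior level:
per-participant condition means first, then a Wilcoxon signed-rank test
across participants for choice proportions (exact p for ≤ 25 non-zero
differences, normal approximation with tie correction otherwise — the z
statistic is always the normal-approximation value, since that is what is
conventionally reported) and a paired t test for judgments. Identical
behaviour in both conditions yields z = 0, p = 1 flagged `degenerate`.
One calibration subtlety: under equal rank weights the baseline and
authority conditions are exchangeable only at the indifference level,
where every scenario's choice distribution is the same coin flip. At
directional levels the conditions differ in their mix of cascade versus
private-favouring scenarios, so the raw contrast rejects under the null
for composition reasons alone; type-I calibration is therefore asserted at
the 0.50 level, and directional-level contrasts should be read as
condition differences, not pure authority effects.

## Numerical and design choices, in one place

* Canonical coding: option `A` ↔ signal `a` throughout; the second option
  and its signal (clinical framing: the `S` diagnosis and its symptom) map
  to `B`/`b` at I/O. Mirrored presentations are generated by
  `mirror_scenario()` (an involution) rather than stored.
* Scenario files carry arbitrary reliabilities and predecessor counts; the
  packaged fixtures pin $2/3$ and ≤ 3 predecessors. The writer emits
  byte-stable CSV/JSON (sorted keys, 6 significant digits).
* Log-odds clipping at ±50; choice probabilities therefore stay within
  machine-safe bounds for all admissible $\theta$.
* Problem sizes used by the tests and scripts: 20-replicate recovery at
  40 × 48 (peer form) and 40 × 40 (rank form); 200 replicate cohorts of 40
  for type-I calibration; one 200-participant cohort for the power check —
  sizes chosen to make Monte-Carlo error small relative to the tolerances
  they are checked against.
* Out of scope by design: hierarchical estimation with hyperpriors (the
  original analysis fits per participant, then averages chains), model
  comparison, noisy/error-prone predecessors, more than two options, and
  non-exchangeable reliabilities.

## Known limitations

The informativeness rule is a reverse-engineered formalisation — it
reproduces every published posterior, but the original verbal description
never states it. The rank form cannot express authority influence from
uninformative decisions, although behavioural data hint such influence may
exist. Published aggregate percentages that are arithmetically inconsistent
with their own per-scenario tables (two directional means and one count)
are reported as computed, not reconciled. And the estimator inherits the
documented small-sample offsets of per-participant Bayesian fitting, so
group HDIs should not be read as exact frequentist confidence intervals.
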