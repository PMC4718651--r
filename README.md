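# socialcascade

Bayesian analysis of social influence in sequential binary decision making.

People deciding in sequence — which urn a ball came from, which of two
diseases a patient has — can use two kinds of evidence: a **private
signal** only they observe, and **public information** in the form of
predecessors' announced decisions, from which those predecessors' private
signals may be inferred. A rational observer who integrates both can end up
in an *information cascade*: once the inferred public evidence leads by two
signals, it is optimal to follow the crowd and ignore one's own draw. This
package implements the normative Bayesian analysis of that problem, a
social influence model that quantifies how strongly people actually weight
private, peer-derived and authority-derived evidence, and the simulation
and estimation machinery needed to study it — aimed at researchers in
judgment and decision making, social learning, and cognitive modelling.

## The model

Signals accumulate on the log-odds scale. With `n_a` a-signals and `n_b`
b-signals of reliability `p = p(a|A) = p(b|B)` and equal priors,

    ln p(A|n_a,n_b)/p(B|n_a,n_b) = Σ_{a-signals} ln p(a|A)/p(a|B)
                                 + Σ_{b-signals} ln p(b|A)/p(b|B),

so only `n_a − n_b` matters (each net signal contributes `ln 2` at
`p = 2/3`). The social influence model re-weights this sum by source,

    β_bias + β_soc · Σ_public f(x) + (2 − β_soc) · Σ_private f(x)

with `f(x) = ln p(x|A)/p(x|B)`, and in the rank-split form

    β_bias + β_HR · Σ_HR f(x) + β_ER · Σ_ER f(x) + (3 − β_HR − β_ER) · Σ_private f(x),

where `HR`/`ER` tag signals inferred from higher/equally ranked sources.
Unit weights and zero bias recover the Bayesian solution; `β_soc < 1`
means private information is overweighted. Choices follow
`p(choose A) = 1/(1 + exp(θ·(p_B − p_A)))` with sensitivity `θ ∈ (0,10)`.
Parameters are estimated per participant by MCMC (truncated-normal prior on
the bias, uniform priors on weights and sensitivity), pooled by averaging
chains, and summarised by medians and 95% highest density intervals.

## Worked example

The classic three-decider situation: two predecessors chose A, the focal
actor draws a b-signal.

```r
library(socialcascade)
s <- scenario("cascade", c("A", "A"), private_signal = "b")
infer_public_signals(s)
#> Signal ledger: public [a(EQ), a(EQ)], private [b] (n_a = 2, n_b = 1)
round(log_odds(infer_public_signals(s)), 2)
#> [1] 0.69
round(scenario_posterior(s), 2)
#> [1] 0.67
```

Both predecessors' decisions are informative, so the focal actor faces two
inferred a-signals against one private b-signal: log odds `0.69` in favour
of A, posterior `0.67` — choosing A against one's own signal is the
rational move, and a cascade has begun. A person with the group-median
fitted parameters (bias −0.12, social weight 0.78, sensitivity 6.08)
overweights the private b-signal:

```r
predict_scenario(s, influence_params(beta_bias = -0.12, beta_soc = 0.78,
                                     theta = 6.08))
#> $subjective_log_odds
#> [1] 0.11567
#> $subjective_posterior_A
#> [1] 0.5288853
#> $choice_prob_A
#> [1] 0.5869195
#> $predicted_judgment
#> [1] 0.5050214
```

— the subjective posterior drops from 0.67 to 0.53, and the predicted
choice of A from 0.89 (the value of the choice rule at the normative
posterior) to 0.59. Group-level aggregates of the packaged response tables
come from derived scenario groupings:

```r
round(printed_aggregates("study1"), 1)
#>             bayes_all bayes_private_favored         cascade_bayes
#>                  86.9                  90.2                  75.5
#>  private_indifference
#>                  79.9
```

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline over the packaged
designs and write tables to `results/`:

1. `01_normative_posteriors.R` — engine posteriors for all 52 designs,
   checked against the published posterior columns.
2. `02_printed_aggregates.R` — scenario-group aggregates of the published
   per-scenario response tables.
3. `03_simulate_cohorts.R` — synthetic cohorts at the published group
   estimates.
4. `04_parameter_recovery.R` — recovery of known parameters from simulated
   cohorts.
5. `05_authority_tests.R` — Wilcoxon/paired-t authority contrasts on a
   rank-weighted cohort.
6. `06_judgment_generalization.R` — choice-only fits predicting probability
   judgments (the compression pattern), with a figure.

Run any of them from the repository root, e.g.
`Rscript analysis/01_normative_posteriors.R`.

## Package layout

* `R/` — scenario engine, influence model, cohort simulator, MCMC fitting,
  reporting layer.
* `inst/extdata/` — the 12 + 40 packaged task designs and published
  per-scenario response summaries (schema in `scenario_schema.md`).
* `vignettes/social-influence-model.Rmd` — the methods vignette: model,
  assumptions, priors, sampler, pooling, and known limitations.
* `tests/testthat/` — unit, property and acceptance tests.
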