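#!/usr/bin/env Rscript
# Authority contrasts: does rank weighting show up in the choice statistics?
#
# Simulates a 200-participant cohort whose authority weight exceeds the peer
# weight by 0.7, then runs the per-level baseline-versus-authority contrasts
# (Wilcoxon signed-rank for private-consistent choice proportions, paired t
# for judgments).

suppressPackageStartupMessages(library(socialcascade))
dir.create("results", showWarnings = FALSE)

design <- load_scenarios("study2")
rec <- simulate_cohort(cohort_spec(
  200, design,
  influence_params(beta_bias = 0, beta_HR = 1.5, beta_ER = 0.8,
                   theta = 6.08, form = "study2"),
  seed = 71))
at <- authority_tests(rec, design)
write.csv(at, "results/authority_tests.csv", row.names = FALSE)
print(at[, c("level", "comparison", "choice_baseline", "choice_condition",
             "z", "p_choice")], digits = 3)
opp <- at[at$comparison == "baseline_vs_opposes" & at$level == 0.5, ]
cat(sprintf("\nAt the indifference level, private-consistent choices drop from
%.2f (baseline) to %.2f when the authority opposes the private signal
(z = %.2f, p = %.2g): the rank-weight difference is clearly detectable.\n",
            opp$choice_baseline, opp$choice_condition, opp$z, opp$p_choice))
cat("Wrote results/authority_tests.csv\n")
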