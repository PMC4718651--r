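#!/usr/bin/env Rscript
# Generalization test: predict probability judgments from choice-only fits.
#
# Simulates an urn-study cohort with private overweighting, fits the model to
# the choices alone, and compares observed mean judgments per posterior level
# with the judgments the fitted model predicts. The fitted model should
# reproduce the compression pattern: above-normative confidence at the 0.50
# level, below-normative confidence at the 0.89 level.

suppressPackageStartupMessages(library(socialcascade))
dir.create("results", showWarnings = FALSE)

design <- load_scenarios("study1", mirrored = TRUE)
truth <- influence_params(beta_bias = -0.12, beta_soc = 0.78, theta = 6.08)
records <- simulate_cohort(cohort_spec(40, design, truth, seed = 21))

fit <- fit_cohort(records, design, "study1", config = chain_config(seed = 22))
pooled <- pool_group(fit)
fitted <- params_from_summary(pooled)
cat("Pooled group estimates (fitted from choices only):\n")
print(pooled)

jc <- judgment_comparison(records, fitted, design)
write.csv(jc, "results/judgment_comparison.csv", row.names = FALSE)
print(round(jc, 3))

pdf("results/judgment_comparison.pdf", width = 5, height = 5)
plot(jc$normative, jc$observed, type = "b", pch = 16, col = "steelblue",
     xlim = c(0.5, 1), ylim = c(0.5, 1),
     xlab = "Normative Bayesian posterior",
     ylab = "Mean probability judgment",
     main = "Observed vs. model-predicted judgments")
lines(jc$normative, jc$predicted, type = "b", pch = 17, col = "seagreen")
abline(0, 1, lty = 2, col = "grey50")
legend("topleft", legend = c("observed", "predicted (choice-only fit)"),
       col = c("steelblue", "seagreen"), pch = c(16, 17), bty = "n")
dev.off()

cat(sprintf("\nPredicted judgment at the 0.50 level: %.3f (above 0.50);
at the 0.89 level: %.3f (below 0.89) — the compression pattern follows from
overweighting private information, without ever fitting the judgments.\n",
            jc$predicted[jc$level == 0.5], jc$predicted[jc$level == 0.89]))
cat("Wrote results/judgment_comparison.csv and .pdf\n")
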