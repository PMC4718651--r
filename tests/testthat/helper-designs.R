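# Shared fixtures: the packaged task designs and the published group-level
# parameter estimates used as simulation ground truths.

study1_designs <- function() load_scenarios("study1")
study2_designs <- function() load_scenarios("study2")

# 24 presentations (12 tasks in both orientations); doubling gives the
# 48-trial recovery design.
study1_mirrored <- function() load_scenarios("study1", mirrored = TRUE)

truth_study1 <- function()
  influence_params(beta_bias = -0.12, beta_soc = 0.78, theta = 6.08)

truth_study2 <- function()
  influence_params(beta_bias = 0.06, beta_HR = 1.12, beta_ER = 0.85,
                   theta = 7.37, form = "study2")

# Printed normative posteriors of the 12 urn-task designs (probability of A).
study1_posteriors <- function()
  c(0.80, 0.89, 0.67, 0.89, 0.80, 0.67, 0.33, 0.67, 0.20, 0.50, 0.50, 0.50)

# Printed posterior levels of the 40 clinical designs (favoured option).
study2_levels <- function()
  c(rep(0.67, 13), rep(0.80, 10), rep(0.89, 7), rep(0.50, 10))

# A tiny constant-sample posterior summary (for pooling/contrast arithmetic).
point_mass_summary <- function(values, n = 200L) {
  samples <- matrix(rep(values, each = n), n, length(values),
                    dimnames = list(NULL, names(values)))
  posterior_summary(samples, chain = rep(1:2, each = n / 2))
}
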