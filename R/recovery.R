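# Parameter-recovery experiments: simulate cohorts at known parameters and
# check that the estimation pipeline retrieves them.

#' Assemble influence parameters from a posterior summary
#'
#' Takes the per-parameter posterior medians of a (typically pooled)
#' [posterior_summary] and returns them as an [influence_params()] object,
#' e.g. for computing model predictions at the group estimate.
#'
#' @param summary A [posterior_summary] whose columns are the parameters of
#'   one model form.
#' @return An [influence_params()].
#' @export
params_from_summary <- function(summary) {
  stopifnot(inherits(summary, "posterior_summary"))
  med <- summary$median
  if ("beta_soc" %in% names(med)) {
    influence_params(beta_bias = med[["beta_bias"]],
                     beta_soc = med[["beta_soc"]],
                     theta = med[["theta"]], form = "study1")
  } else {
    influence_params(beta_bias = med[["beta_bias"]],
                     beta_HR = med[["beta_HR"]], beta_ER = med[["beta_ER"]],
                     theta = med[["theta"]], form = "study2")
  }
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates cohorts at a fixed known parameter vector, fits every
#' participant by MCMC, pools the chains into a group posterior, and records
#' the pooled medians and whether each 95% HDI covers the truth.
#'
#' @param truth An [influence_params()] used as the fixed simulation truth.
#' @param design Scenario list (repeats allowed) or fixture name.
#' @param n_participants Participants per cohort.
#' @param n_replicates Number of replicate cohorts.
#' @param config A [chain_config()] for the fits.
#' @param judgment_noise_sd Probability-scale judgment noise of the
#'   simulated cohorts (judgments do not enter the fits).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A list with `replicates` (data frame of pooled medians, HDI
#'   bounds and coverage per replicate and parameter), `median_estimates`
#'   (across-replicate means of the pooled medians), `coverage`
#'   (per-parameter HDI coverage rates), and `truth`.
#' @export
recovery_experiment <- function(truth, design, n_participants = 40L,
                                n_replicates = 20L, config = chain_config(),
                                judgment_noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "influence_params"))
  if (is.character(design)) design <- load_scenarios(design)
  nm <- param_names(truth$form)
  truth_vec <- vapply(nm, function(p) truth[[p]], numeric(1))
  rows <- list()
  for (r in seq_len(n_replicates)) {
    sim_seed <- derive_seed(seed, 2L * r)
    fit_seed <- derive_seed(seed, 2L * r + 1L)
    records <- simulate_cohort(cohort_spec(
      n_participants = n_participants, design = design, params = truth,
      judgment_noise_sd = judgment_noise_sd, seed = sim_seed))
    cfg <- config
    cfg$seed <- fit_seed
    fit <- fit_cohort(records, design, form = truth$form, config = cfg)
    pooled <- pool_group(fit)
    rows[[r]] <- data.frame(
      replicate = r, parameter = nm, truth = truth_vec,
      median = pooled$median[nm],
      hdi_lower = pooled$hdi_lower[nm], hdi_upper = pooled$hdi_upper[nm],
      covered = pooled$hdi_lower[nm] <= truth_vec &
        truth_vec <= pooled$hdi_upper[nm],
      converged = pooled$converged,
      stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  med <- tapply(reps$median, reps$parameter, mean)[nm]
  cov <- tapply(reps$covered, reps$parameter, mean)[nm]
  list(replicates = reps, median_estimates = med, coverage = cov,
       truth = truth_vec)
}
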