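# Synthetic participant cohorts with known influence parameters.

# Deterministic per-participant substream seeds: cohorts are extensible
# (adding participants never reshuffles earlier ones). Kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 32611 + 104729 * i) %% 2147483629L
}

# Truncated normal draw via inverse-CDF (deterministic under set.seed).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

param_bounds <- function(name) {
  switch(name,
         beta_bias = c(-1, 1),
         beta_soc = c(0, 2), beta_HR = c(0, 2), beta_ER = c(0, 2),
         theta = c(0, 10),
         stop("unknown parameter: ", name))
}

param_names <- function(form) {
  if (form == "study1") c("beta_bias", "beta_soc", "theta")
  else c("beta_bias", "beta_HR", "beta_ER", "theta")
}

#' Specify a synthetic cohort
#'
#' Defines the generative conditions for a cohort of simulated participants:
#' the scenario design each participant answers, the population distribution
#' of influence parameters (independent truncated Gaussians around the given
#' means, or fixed values when `param_sd` is zero), the probability-scale
#' judgment noise, and the master seed.
#'
#' @param n_participants Number of participants (> 0).
#' @param design Scenario list, or a fixture name understood by
#'   [load_scenarios()]. Repeated scenarios are allowed and count as repeated
#'   trials.
#' @param params An [influence_params()] giving the population means (or the
#'   fixed truth).
#' @param param_sd Named numeric vector of population standard deviations per
#'   parameter (missing names default to 0, i.e. fixed). Draws are truncated
#'   to the legal parameter ranges.
#' @param judgment_noise_sd Gaussian noise added to the noiseless judgment on
#'   the probability scale before clamping to \[0.5, 1\]. Default 0.05.
#' @param judgment_rule Passed to the prediction layer (`"expected"` or
#'   `"argmax"`); judgments are centred on the subjective posterior of the
#'   option actually chosen, so this only affects reporting layers.
#' @param seed Master seed; per-participant substreams are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, design, params,
                        param_sd = numeric(0), judgment_noise_sd = 0.05,
                        judgment_rule = "expected", seed = 1L) {
  if (is.character(design)) design <- load_scenarios(design)
  stopifnot(n_participants > 0, judgment_noise_sd >= 0,
            inherits(params, "influence_params"),
            all(vapply(design, inherits, logical(1), "decision_scenario")))
  if (length(param_sd) && is.null(names(param_sd)))
    stop("`param_sd` must be a named vector")
  bad <- setdiff(names(param_sd), param_names(params$form))
  if (length(bad)) stop("unknown parameter(s) in `param_sd`: ",
                        paste(bad, collapse = ", "))
  if (any(param_sd < 0)) stop("`param_sd` entries must be non-negative")
  structure(list(n_participants = as.integer(n_participants), design = design,
                 params = params, param_sd = param_sd,
                 judgment_noise_sd = judgment_noise_sd,
                 judgment_rule = judgment_rule, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_participant_params <- function(spec) {
  nm <- param_names(spec$params$form)
  means <- vapply(nm, function(p) spec$params[[p]], numeric(1))
  sds <- vapply(nm, function(p)
    if (p %in% names(spec$param_sd)) spec$param_sd[[p]] else 0, numeric(1))
  draws <- vapply(seq_along(nm), function(j) {
    b <- param_bounds(nm[j])
    rtruncnorm1(1L, means[j], sds[j], b[1], b[2])
  }, numeric(1))
  names(draws) <- nm
  draws
}

#' Simulate a cohort of participants
#'
#' For each participant, draws influence parameters from the population
#' distribution of the [cohort_spec()], then for every scenario in the
#' design draws the choice from the model's choice probability and a
#' probability judgment centred on the subjective posterior of the chosen
#' option, with truncated Gaussian noise on the probability scale (clamped
#' to \[0.5, 1\]). Fully reproducible from the master seed; each participant
#' uses a deterministic substream.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of records with columns `participant_id`,
#'   `scenario_id`, `choice`, `judgment`; the per-participant true parameters
#'   are attached as the `truth` attribute (a data frame).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  scens <- spec$design
  form <- spec$params$form
  feat <- scenario_features(scens)
  nm <- param_names(form)
  n_s <- length(scens)
  recs <- vector("list", spec$n_participants)
  truth <- matrix(NA_real_, spec$n_participants, length(nm),
                  dimnames = list(NULL, nm))
  for (i in seq_len(spec$n_participants)) {
    set.seed(derive_seed(spec$seed, i))
    par_i <- draw_participant_params(spec)
    truth[i, ] <- par_i
    probs <- model_probs(matrix(par_i, 1, dimnames = list(NULL, nm)), feat, form)
    pc <- probs$choice[1, ]
    ps <- probs$posterior[1, ]
    choose_A <- stats::runif(n_s) < pc
    ps_chosen <- ifelse(choose_A, ps, 1 - ps)
    judgment <- ps_chosen + stats::rnorm(n_s, 0, spec$judgment_noise_sd)
    recs[[i]] <- data.frame(
      participant_id = sprintf("p%03d", i),
      scenario_id = vapply(scens, function(s) s$scenario_id, character(1)),
      choice = ifelse(choose_A, "A", "B"),
      judgment = pmin(pmax(judgment, 0.5), 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(participant_id = sprintf("p%03d",
                                     seq_len(spec$n_participants)),
                                   truth, stringsAsFactors = FALSE)
  attr(out, "cohort_spec") <- spec
  out
}

#' Simulate a cohort of ideal Bayesian responders
#'
#' Convenience wrapper around [simulate_cohort()] fixing the influence
#' weights at the Bayesian point (unit weights, zero bias) with the given
#' sensitivity; used for model-recovery null checks.
#'
#' @param n Number of participants.
#' @param design Scenario list or fixture name.
#' @param theta Choice sensitivity.
#' @param seed Master seed.
#' @param judgment_noise_sd Probability-scale judgment noise (default 0).
#' @return Records data frame as from [simulate_cohort()].
#' @export
simulate_bayesian_cohort <- function(n, design, theta, seed = 1L,
                                     judgment_noise_sd = 0) {
  simulate_cohort(cohort_spec(
    n_participants = n, design = design,
    params = influence_params(beta_bias = 0, beta_soc = 1, theta = theta,
                              form = "study1"),
    judgment_noise_sd = judgment_noise_sd, seed = seed))
}

#' Write cohort records and truth tables to CSV
#'
#' @param records Records from [simulate_cohort()].
#' @param records_path,truth_path Output paths; the truth table is written
#'   only when `truth_path` is given.
#' @return `records_path`, invisibly.
#' @export
write_cohort <- function(records, records_path, truth_path = NULL) {
  utils::write.csv(records, records_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path))
    utils::write.csv(attr(records, "truth"), truth_path, row.names = FALSE,
                     quote = FALSE)
  invisible(records_path)
}
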