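# The social influence model: differentially weighted log-odds evidence
# integration and the sensitivity-based choice rule.

LOG_ODDS_CLIP <- 50  # numerical guard before exponentiation

#' Social influence model parameters
#'
#' The model re-weights the normative log-odds evidence sum by source. In the
#' `study1` form, public (socially inferred) signals receive weight
#' `beta_soc` and private signals the complementary weight `2 - beta_soc`,
#' so the total weight is conserved at 2 and `beta_soc = 1` recovers equal
#' (Bayesian) weighting. In the `study2` form, public signals are split by
#' the source's hierarchical rank: weight `beta_HR` for higher ranked
#' sources, `beta_ER` for equally ranked sources, and `3 - beta_HR -
#' beta_ER` for private signals, so `beta_HR = beta_ER = 1` again recovers
#' the Bayesian solution. `beta_bias` is an additive prior log-odds shift
#' toward option A, and `theta` is the choice sensitivity of the response
#' rule (see [choice_probability()]).
#'
#' @param beta_bias Additive bias (log-odds units), in \[-1, 1\] under the
#'   default priors.
#' @param beta_soc Social weight for the `study1` form, in (0, 2).
#' @param beta_HR,beta_ER Authority and peer weights for the `study2` form,
#'   each in (0, 2) under the default priors.
#' @param theta Choice sensitivity, in (0, 10).
#' @param form `"study1"` or `"study2"`.
#' @return An object of class `influence_params`.
#' @examples
#' influence_params(beta_soc = 1, beta_bias = 0, theta = 6)  # Bayesian weighting
#' @export
influence_params <- function(beta_bias = 0, beta_soc = NULL, beta_HR = NULL,
                             beta_ER = NULL, theta = 5,
                             form = c("study1", "study2")) {
  form <- match.arg(if (is.null(beta_soc) && (!is.null(beta_HR) || !is.null(beta_ER)))
    "study2" else form, c("study1", "study2"))
  if (form == "study1") {
    if (is.null(beta_soc)) beta_soc <- 1
    if (beta_soc <= 0 || beta_soc >= 2)
      stop("`beta_soc` must lie in (0, 2)")
  } else {
    if (is.null(beta_HR)) beta_HR <- 1
    if (is.null(beta_ER)) beta_ER <- 1
  }
  if (theta <= 0 || theta >= 10) stop("`theta` must lie in (0, 10)")
  structure(list(beta_bias = beta_bias, beta_soc = beta_soc,
                 beta_HR = beta_HR, beta_ER = beta_ER, theta = theta,
                 form = form),
            class = "influence_params")
}

#' @export
print.influence_params <- function(x, ...) {
  if (x$form == "study1")
    cat(sprintf(
      "Influence params (study1 form): beta_bias = %.3f, beta_soc = %.3f, theta = %.3f\n",
      x$beta_bias, x$beta_soc, x$theta))
  else
    cat(sprintf(
      "Influence params (study2 form): beta_bias = %.3f, beta_HR = %.3f, beta_ER = %.3f, theta = %.3f\n",
      x$beta_bias, x$beta_HR, x$beta_ER, x$theta))
  invisible(x)
}

#' Subjectively weighted log odds of option A
#'
#' Applies the social influence model's source weights to the per-signal
#' log-likelihood ratios of a ledger. In the `study1` form public signals
#' are weighted `beta_soc` and private signals `2 - beta_soc`; in the
#' `study2` form public signals are weighted by source rank (`beta_HR` for
#' higher ranked, `beta_ER` for equally ranked) and private signals
#' `3 - beta_HR - beta_ER`. `beta_bias` is added. At the Bayesian point
#' (all weights 1, zero bias) the result equals [log_odds()] with equal
#' priors.
#'
#' @param ledger A `signal_ledger`.
#' @param params An [influence_params()].
#' @param spec A [likelihood_spec()] (its prior enters only through
#'   `beta_bias`, which absorbs any prior log odds).
#' @return Subjective log odds of A over B, clipped to ±50.
#' @export
weighted_log_odds <- function(ledger, params, spec = likelihood_spec()) {
  stopifnot(inherits(ledger, "signal_ledger"), inherits(params, "influence_params"))
  f_pub <- signal_loglr(ledger$public$signal, spec)
  f_priv <- signal_loglr(ledger$private, spec)
  l <- if (params$form == "study1") {
    params$beta_bias + params$beta_soc * sum(f_pub) +
      (2 - params$beta_soc) * sum(f_priv)
  } else {
    if (nrow(ledger$public) > 0 && any(!ledger$public$rank %in% RANKS))
      stop("study2 form requires every public signal tagged EQ or HR")
    params$beta_bias +
      params$beta_HR * sum(f_pub[ledger$public$rank == "HR"]) +
      params$beta_ER * sum(f_pub[ledger$public$rank == "EQ"]) +
      (3 - params$beta_HR - params$beta_ER) * sum(f_priv)
  }
  max(min(l, LOG_ODDS_CLIP), -LOG_ODDS_CLIP)
}

#' Choice probability from posterior probabilities
#'
#' The response rule maps the (subjective) posterior difference between the
#' two options to a choice probability through the sensitivity `theta`:
#' `p(choose A) = 1 / (1 + exp(theta * (p_B - p_A)))`. At `theta = 0` the
#' rule is insensitive (both options chosen with probability one half); as
#' `theta` grows, the option with the higher posterior is chosen ever more
#' deterministically.
#'
#' @param posterior_A,posterior_B Posterior probabilities of the two options
#'   (must sum to 1).
#' @param theta Non-negative sensitivity.
#' @return Probability of choosing option A.
#' @examples
#' choice_probability(0.67, 0.33, 6.08)  # about 0.89
#' @export
choice_probability <- function(posterior_A, posterior_B = 1 - posterior_A,
                               theta) {
  stopifnot(all(abs(posterior_A + posterior_B - 1) < 1e-9), all(theta >= 0))
  stats::plogis(theta * (posterior_A - posterior_B))
}

#' Model predictions for one scenario
#'
#' Pipes the signal-inference engine through the weighted evidence
#' integration and the choice rule, returning the subjective log odds, the
#' subjective posterior of A, the choice probability of A, and the predicted
#' probability judgment. The predicted judgment is, by default, the
#' expectation over the model's own choice distribution of the subjective
#' posterior of the chosen option,
#' `p(choose A) * p_subj(A) + p(choose B) * p_subj(B)`, which is always at
#' least one half; `judgment_rule = "argmax"` instead reports the subjective
#' posterior of the modal option, `max(p_subj, 1 - p_subj)`.
#'
#' @param scenario A valid [scenario()].
#' @param params An [influence_params()].
#' @param judgment_rule `"expected"` (default) or `"argmax"`.
#' @return A list of class `model_prediction` with fields
#'   `subjective_log_odds`, `subjective_posterior_A`, `choice_prob_A`,
#'   `predicted_judgment`.
#' @export
predict_scenario <- function(scenario, params,
                             judgment_rule = c("expected", "argmax")) {
  judgment_rule <- match.arg(judgment_rule)
  ledger <- infer_public_signals(scenario)
  l <- weighted_log_odds(ledger, params, scenario$likelihood)
  ps <- stats::plogis(l)
  pc <- choice_probability(ps, 1 - ps, params$theta)
  judgment <- switch(judgment_rule,
                     expected = pc * ps + (1 - pc) * (1 - ps),
                     argmax = max(ps, 1 - ps))
  structure(list(subjective_log_odds = l, subjective_posterior_A = ps,
                 choice_prob_A = pc, predicted_judgment = judgment),
            class = "model_prediction")
}

#' Model predictions for a scenario set, as a data frame
#'
#' @param scenarios List of `decision_scenario` objects.
#' @param params An [influence_params()].
#' @param judgment_rule Passed to [predict_scenario()].
#' @return Data frame keyed by `scenario_id` with the four prediction fields.
#' @export
predict_scenarios <- function(scenarios, params,
                              judgment_rule = c("expected", "argmax")) {
  judgment_rule <- match.arg(judgment_rule)
  rows <- lapply(scenarios, function(s) {
    p <- predict_scenario(s, params, judgment_rule)
    data.frame(scenario_id = s$scenario_id,
               subjective_log_odds = p$subjective_log_odds,
               subjective_posterior_A = p$subjective_posterior_A,
               choice_prob_A = p$choice_prob_A,
               predicted_judgment = p$predicted_judgment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-scenario sufficient statistics for vectorised likelihoods: signed sums
# of per-signal log-likelihood ratios by source class. For scenario s and
# parameter vector (bias, weights...), the subjective log odds are
#   study1: bias + beta_soc * pub + (2 - beta_soc) * priv
#   study2: bias + beta_HR * hr + beta_ER * er + (3 - beta_HR - beta_ER) * priv
scenario_features <- function(scenarios) {
  feat <- lapply(scenarios, function(s) {
    ledger <- infer_public_signals(s)
    f_pub <- signal_loglr(ledger$public$signal, s$likelihood)
    c(pub = sum(f_pub),
      hr = sum(f_pub[ledger$public$rank == "HR"]),
      er = sum(f_pub[ledger$public$rank == "EQ"]),
      priv = sum(signal_loglr(ledger$private, s$likelihood)))
  })
  m <- do.call(rbind, feat)
  rownames(m) <- vapply(scenarios, function(s) s$scenario_id, character(1))
  m
}

# Vectorised model evaluation: params matrix (rows = parameter vectors,
# columns per `form`) times feature matrix (rows = scenarios). Returns a
# list of matrices [n_param_rows x n_scenarios]: subjective posterior of A
# and choice probability of A.
model_probs <- function(par, feat, form) {
  bias <- par[, "beta_bias"]
  l <- if (form == "study1") {
    outer(par[, "beta_soc"], feat[, "pub"]) +
      outer(2 - par[, "beta_soc"], feat[, "priv"]) + bias
  } else {
    outer(par[, "beta_HR"], feat[, "hr"]) +
      outer(par[, "beta_ER"], feat[, "er"]) +
      outer(3 - par[, "beta_HR"] - par[, "beta_ER"], feat[, "priv"]) + bias
  }
  l <- pmin(pmax(l, -LOG_ODDS_CLIP), LOG_ODDS_CLIP)
  ps <- stats::plogis(l)
  pc <- stats::plogis(par[, "theta"] * (2 * ps - 1))
  list(posterior = ps, choice = pc)
}
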