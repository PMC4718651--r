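# Per-participant Bayesian estimation of the social influence model by
# random-walk Metropolis sampling, with chain pooling, HDI summaries, and
# parameter contrasts.

#' Prior specification for the influence parameters
#'
#' The bias weight gets a truncated normal prior (mean zero, configurable
#' standard deviation, truncated at ±1, enforced by rejection); the source
#' weights get uniform priors on (0, 2); the sensitivity gets a uniform
#' prior on (0, 10).
#'
#' @param form `"study1"` or `"study2"` (selects which source weights exist).
#' @param bias_sd Standard deviation of the bias prior before truncation.
#'   Default 10, which is effectively flat on \[-1, 1\].
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(form = c("study1", "study2"), bias_sd = 10) {
  form <- match.arg(form)
  stopifnot(bias_sd > 0)
  structure(list(form = form, bias_sd = bias_sd), class = "prior_spec")
}

prior_log_density <- function(par, prior) {
  lp <- stats::dnorm(par[, "beta_bias"], 0, prior$bias_sd, log = TRUE)
  lp[abs(par[, "beta_bias"]) > 1] <- -Inf
  for (w in intersect(colnames(par), c("beta_soc", "beta_HR", "beta_ER")))
    lp[par[, w] <= 0 | par[, w] >= 2] <- -Inf
  lp[par[, "theta"] <= 0 | par[, "theta"] >= 10] <- -Inf
  lp
}

prior_draw <- function(n, prior) {
  nm <- param_names(prior$form)
  out <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  out[, "beta_bias"] <- rtruncnorm1(n, 0, prior$bias_sd, -1, 1)
  for (w in setdiff(nm, c("beta_bias", "theta")))
    out[, w] <- stats::runif(n, 0, 2)
  out[, "theta"] <- stats::runif(n, 0, 10)
  out
}

#' Markov chain configuration
#'
#' The `"paper"` profile mirrors the original estimation settings (burn-in
#' 10,000 iterations, thinning factor 100, about 50,000 kept samples across
#' chains); the `"desk"` profile (the default) keeps 5,000 samples across 4
#' chains with a short burn-in, which is sufficient for the low-dimensional
#' posteriors involved and runs in seconds.
#'
#' @param profile `"desk"` or `"paper"`; sets defaults for the other
#'   arguments, each of which can be overridden.
#' @param n_chains Number of independent chains (>= 2 enables convergence
#'   diagnostics).
#' @param burn_in Discarded initial iterations per chain.
#' @param thinning Keep every `thinning`-th post-burn-in iteration.
#' @param kept Kept samples per chain.
#' @param seed Sampler seed.
#' @param proposal_sd Optional named vector of random-walk proposal standard
#'   deviations per parameter.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(profile = c("desk", "paper"), n_chains = 4L,
                         burn_in = NULL, thinning = NULL, kept = NULL,
                         seed = 1L, proposal_sd = NULL) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
                     desk = list(burn_in = 1000L, thinning = 8L, kept = 1250L),
                     paper = list(burn_in = 10000L, thinning = 100L,
                                  kept = 12500L))
  burn_in <- as.integer(if (is.null(burn_in)) defaults$burn_in else burn_in)
  thinning <- as.integer(if (is.null(thinning)) defaults$thinning else thinning)
  kept <- as.integer(if (is.null(kept)) defaults$kept else kept)
  if (kept <= 0L) stop("`kept` must be positive: a chain of 0 samples is empty")
  if (burn_in < 0L || thinning <= 0L || n_chains <= 0L)
    stop("`burn_in` must be >= 0 and `thinning`, `n_chains` positive")
  structure(list(profile = profile, n_chains = as.integer(n_chains),
                 burn_in = burn_in, thinning = thinning, kept = kept,
                 seed = as.integer(seed), proposal_sd = proposal_sd),
            class = "chain_config")
}

default_proposal_sd <- function(nm) {
  sd <- c(beta_bias = 0.15, beta_soc = 0.2, beta_HR = 0.2, beta_ER = 0.2,
          theta = 0.8)
  sd[nm]
}

#' Bernoulli log likelihood of choices under the influence model
#'
#' Sums, over a participant's trials, the log probability of the observed
#' choice under the model's choice rule. Probability judgments are *not*
#' part of the likelihood: the model is estimated from choices alone, which
#' is what makes predicting judgments a genuine generalization test.
#'
#' @param records Data frame with columns `scenario_id` and `choice`.
#' @param params An [influence_params()].
#' @param scenarios Named list of scenarios resolving every
#'   `records$scenario_id`.
#' @return The log likelihood (a single number).
#' @export
log_likelihood <- function(records, params, scenarios) {
  stopifnot(inherits(params, "influence_params"))
  names(scenarios) <- vapply(scenarios, function(s) s$scenario_id, character(1))
  scenarios <- scenarios[!duplicated(names(scenarios))]
  missing <- setdiff(unique(records$scenario_id), names(scenarios))
  if (length(missing))
    stop("records reference unknown scenario(s): ", paste(missing, collapse = ", "))
  if (nrow(records) == 0L) return(0)
  feat <- scenario_features(scenarios)
  nm <- param_names(params$form)
  par <- matrix(vapply(nm, function(p) params[[p]], numeric(1)), 1,
                dimnames = list(NULL, nm))
  pc <- model_probs(par, feat, params$form)$choice[1, ]
  names(pc) <- names(scenarios)
  p_rec <- ifelse(records$choice == "A", pc[records$scenario_id],
                  1 - pc[records$scenario_id])
  sum(log(p_rec))
}

count_matrices <- function(records, scenario_ids, participants) {
  kA <- matrix(0, length(participants), length(scenario_ids),
               dimnames = list(participants, scenario_ids))
  n <- kA
  if (nrow(records)) {
    tab_n <- table(factor(records$participant_id, participants),
                   factor(records$scenario_id, scenario_ids))
    tab_a <- table(factor(records$participant_id[records$choice == "A"],
                          participants),
                   factor(records$scenario_id[records$choice == "A"],
                          scenario_ids))
    n[] <- tab_n
    kA[] <- tab_a
  }
  list(kA = kA, n = n)
}

#' Fit the influence model to every participant in a record set
#'
#' Samples each participant's posterior over the influence parameters by
#' random-walk Metropolis, vectorised across participants and chains (all
#' participants are independent, so their chains advance in lock-step).
#' The posterior is prior × Bernoulli choice likelihood; judgments are
#' ignored by construction. Chains are initialised from the prior, and
#' convergence is monitored per participant and parameter with split-R-hat
#' (flagged, never silently dropped, when any exceeds 1.01).
#'
#' @param records Records data frame (`participant_id`, `scenario_id`,
#'   `choice`).
#' @param scenarios Named list of scenarios resolving the record set.
#' @param form Model form, `"study1"` or `"study2"`.
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @return An object of class `cascade_fit`: a list with `summaries` (one
#'   [posterior_summary] per participant), `form`, `prior`, `config`.
#' @export
fit_cohort <- function(records, scenarios, form = c("study1", "study2"),
                       prior = NULL, config = chain_config()) {
  form <- match.arg(form)
  if (is.null(prior)) prior <- prior_spec(form)
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "chain_config"),
            prior$form == form)
  names(scenarios) <- vapply(scenarios, function(s) s$scenario_id, character(1))
  scenarios <- scenarios[!duplicated(names(scenarios))]  # designs may repeat trials
  missing <- setdiff(unique(records$scenario_id), names(scenarios))
  if (length(missing))
    stop("records reference unknown scenario(s): ", paste(missing, collapse = ", "))
  participants <- if (nrow(records)) unique(records$participant_id) else "p001"
  np <- length(participants)
  nc <- config$n_chains
  nm <- param_names(form)
  k <- length(nm)
  feat <- scenario_features(scenarios)
  cm <- count_matrices(records, names(scenarios), participants)
  rep_idx <- rep(seq_len(np), nc)            # row -> participant
  kA <- cm$kA[rep_idx, , drop = FALSE]
  n_tr <- cm$n[rep_idx, , drop = FALSE]
  nrows <- np * nc

  log_post <- function(par) {
    lp <- prior_log_density(par, prior)
    ok <- is.finite(lp)
    if (any(ok)) {
      pc <- model_probs(par[ok, , drop = FALSE], feat, form)$choice
      lp[ok] <- lp[ok] + rowSums(kA[ok, , drop = FALSE] * log(pc) +
                                   (n_tr[ok, , drop = FALSE] -
                                      kA[ok, , drop = FALSE]) * log1p(-pc))
    }
    lp
  }

  prop_sd <- if (is.null(config$proposal_sd)) default_proposal_sd(nm)
             else config$proposal_sd[nm]
  if (anyNA(prop_sd)) stop("`proposal_sd` must name every parameter of the form")

  set.seed(config$seed)
  cur <- prior_draw(nrows, prior)
  lp_cur <- log_post(cur)
  keep <- array(NA_real_, c(config$kept, nrows, k),
                dimnames = list(NULL, NULL, nm))
  total <- config$burn_in + config$kept * config$thinning
  kept_i <- 0L
  for (it in seq_len(total)) {
    prop <- cur + matrix(stats::rnorm(nrows * k), nrows, k) *
      rep(prop_sd, each = nrows)
    lp_prop <- log_post(prop)
    acc <- log(stats::runif(nrows)) < (lp_prop - lp_cur)
    cur[acc, ] <- prop[acc, ]
    lp_cur[acc] <- lp_prop[acc]
    if (it > config$burn_in && (it - config$burn_in) %% config$thinning == 0L) {
      kept_i <- kept_i + 1L
      keep[kept_i, , ] <- cur
    }
  }

  summaries <- lapply(seq_len(np), function(i) {
    rows <- i + (seq_len(nc) - 1L) * np
    samples <- do.call(rbind, lapply(rows, function(r) keep[, r, , drop = TRUE]))
    if (k == 1L) samples <- matrix(samples, ncol = 1L, dimnames = list(NULL, nm))
    chain <- rep(seq_len(nc), each = config$kept)
    rhat <- vapply(nm, function(p)
      split_rhat(matrix(samples[, p], config$kept, nc)), numeric(1))
    posterior_summary(samples, chain = chain, rhat = rhat,
                      id = participants[i])
  })
  names(summaries) <- participants
  structure(list(summaries = summaries, form = form, prior = prior,
                 config = config),
            class = "cascade_fit")
}

#' Fit the influence model for a single participant
#'
#' Convenience wrapper around [fit_cohort()] for one participant's records;
#' with zero records the posterior equals the prior.
#'
#' @inheritParams fit_cohort
#' @return A [posterior_summary].
#' @export
fit_participant <- function(records, scenarios, form = c("study1", "study2"),
                            prior = NULL, config = chain_config()) {
  form <- match.arg(form)
  if (nrow(records) && length(unique(records$participant_id)) != 1L)
    stop("`fit_participant()` expects records of exactly one participant")
  fit <- fit_cohort(records, scenarios, form, prior, config)
  fit$summaries[[1L]]
}

#' Posterior summary container
#'
#' Holds kept posterior samples (rows) per parameter (columns) with their
#' chain indices, plus medians, 95% HDI bounds, split-R-hat diagnostics,
#' and a convergence flag (any R-hat above 1.01 marks the summary as not
#' converged).
#'
#' @param samples Numeric matrix of kept samples, columns named by parameter.
#' @param chain Integer vector of chain indices (one per row).
#' @param rhat Optional named vector of split-R-hat values (computed from
#'   `samples`/`chain` when omitted).
#' @param id Optional participant or group label.
#' @param hdi_mass Probability mass of the reported HDIs.
#' @return An object of class `posterior_summary`.
#' @export
posterior_summary <- function(samples, chain = rep(1L, nrow(samples)),
                              rhat = NULL, id = NULL, hdi_mass = 0.95) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(chain), !is.null(colnames(samples)))
  if (is.null(rhat)) {
    nc <- length(unique(chain))
    kept <- nrow(samples) / nc
    rhat <- vapply(colnames(samples), function(p)
      if (nc >= 2L && kept == floor(kept))
        split_rhat(matrix(samples[order(chain), p], kept, nc)) else NA_real_,
      numeric(1))
  }
  med <- apply(samples, 2, stats::median)
  hdis <- apply(samples, 2, hdi, mass = hdi_mass)
  structure(list(id = id, samples = samples, chain = chain,
                 median = med, hdi_lower = hdis[1, ], hdi_upper = hdis[2, ],
                 rhat = rhat, hdi_mass = hdi_mass,
                 converged = all(is.na(rhat) | rhat < 1.01)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary%s (%d kept samples, %d chain(s)%s)\n",
              if (is.null(x$id)) "" else paste0(" for ", x$id),
              nrow(x$samples), length(unique(x$chain)),
              if (x$converged) "" else "; NOT CONVERGED"))
  df <- data.frame(median = x$median, hdi_lower = x$hdi_lower,
                   hdi_upper = x$hdi_upper, rhat = x$rhat)
  print(round(df, 3))
  invisible(x)
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat(sprintf("Influence-model fit (%s form): %d participant(s), %s chains x %d kept\n",
              x$form, length(x$summaries), x$config$n_chains, x$config$kept))
  med <- t(vapply(x$summaries, function(s) s$median,
                  numeric(length(param_names(x$form)))))
  cat("Across-participant quartiles of posterior medians:\n")
  print(round(apply(med, 2, stats::quantile, c(0.25, 0.5, 0.75)), 3))
  invisible(x)
}

#' Pool participants' posterior chains into a group posterior
#'
#' The group distribution is formed by averaging participants' Markov chains
#' sample-wise (sample *i* of the group chain is the mean over participants
#' of their sample *i*, within each chain), then summarised by median and
#' HDI. Pooling is invariant to participant order, and pooling a single
#' participant is the identity. Chains of unequal kept length are first
#' thinned evenly to the shortest length. `method = "concatenate"` instead
#' stacks participants' samples within each chain, giving the mixture rather
#' than the distribution of the mean.
#'
#' @param fits A `cascade_fit` or a list of [posterior_summary] objects.
#' @param method `"average"` (default) or `"concatenate"`.
#' @return A [posterior_summary] for the group.
#' @export
pool_group <- function(fits, method = c("average", "concatenate")) {
  method <- match.arg(method)
  if (inherits(fits, "cascade_fit")) fits <- fits$summaries
  if (inherits(fits, "posterior_summary")) fits <- list(fits)
  if (length(fits) == 0L) stop("`pool_group()` needs at least one summary")
  stopifnot(all(vapply(fits, inherits, logical(1), "posterior_summary")))
  kmin <- min(vapply(fits, function(s) nrow(s$samples), integer(1)))
  harmon <- lapply(fits, function(s) {
    if (nrow(s$samples) == kmin) return(s)
    idx <- unique(round(seq(1, nrow(s$samples), length.out = kmin)))
    list(samples = s$samples[idx, , drop = FALSE], chain = s$chain[idx])
  })
  chain <- harmon[[1]]$chain
  if (method == "average") {
    pooled <- Reduce(`+`, lapply(harmon, function(s) s$samples)) / length(harmon)
  } else {
    pooled <- do.call(rbind, lapply(harmon, function(s) s$samples))
    chain <- unlist(lapply(harmon, function(s) s$chain))
  }
  posterior_summary(pooled, chain = chain, id = "group")
}

#' Posterior of a derived parameter contrast
#'
#' Computes sample-wise arithmetic on a posterior's chains for the named
#' contrast and summarises the derived quantity. Available contrasts:
#' `private_minus_public_s1` (`(2 - beta_soc) - beta_soc`, study-1 form),
#' and for the study-2 form `HR_minus_ER` (`beta_HR - beta_ER`),
#' `private_minus_ER` and `private_minus_HR` (private weight
#' `3 - beta_HR - beta_ER` minus the respective public weight), and
#' `private_weight` (`3 - beta_HR - beta_ER` itself).
#'
#' @param x A [posterior_summary] (typically the pooled group posterior).
#' @param which Contrast name.
#' @return A [posterior_summary] of the derived quantity.
#' @export
contrast <- function(x, which = c("private_minus_public_s1", "HR_minus_ER",
                                  "private_minus_ER", "private_minus_HR",
                                  "private_weight")) {
  which <- match.arg(which)
  stopifnot(inherits(x, "posterior_summary"))
  s <- x$samples
  need <- if (which == "private_minus_public_s1") "beta_soc"
          else c("beta_HR", "beta_ER")
  if (!all(need %in% colnames(s)))
    stop(sprintf("contrast `%s` requires parameter(s) %s: wrong model form",
                 which, paste(need, collapse = ", ")))
  d <- switch(which,
              private_minus_public_s1 = 2 - 2 * s[, "beta_soc"],
              HR_minus_ER = s[, "beta_HR"] - s[, "beta_ER"],
              private_minus_ER = 3 - s[, "beta_HR"] - 2 * s[, "beta_ER"],
              private_minus_HR = 3 - 2 * s[, "beta_HR"] - s[, "beta_ER"],
              private_weight = 3 - s[, "beta_HR"] - s[, "beta_ER"])
  posterior_summary(matrix(d, ncol = 1, dimnames = list(NULL, which)),
                    chain = x$chain, id = x$id)
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous interval containing the target probability mass,
#' found by sliding a fixed-size window over the sorted samples.
#'
#' @param samples Numeric vector (at least 100 values).
#' @param mass Target mass, default 0.95.
#' @return Length-2 vector `(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  n <- length(samples)
  if (n < 100L) stop("`hdi()` needs at least 100 samples")
  s <- sort(samples)
  m <- ceiling(mass * n)
  widths <- s[m:n] - s[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Split-R-hat convergence diagnostic
#'
#' Splits each chain in half and computes the potential scale reduction
#' factor over the resulting half-chains; values near 1 indicate that the
#' chains have mixed.
#'
#' @param chains Numeric matrix, one column per chain.
#' @return The split-R-hat value.
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  half <- floor(n / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(1)
  B <- half * stats::var(means)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}
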