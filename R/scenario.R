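#' Signal reliability and prior specification
#'
#' Describes the evidence structure of a two-option sequential decision task:
#' each decision maker receives one binary private signal (`"a"` or `"b"`)
#' whose reliability is the probability of observing the option-consistent
#' signal given the true state, e.g. `p(a | A)`. Reliabilities are assumed
#' exchangeable between the two options, so `p(b | B)` equals `p(a | A)`.
#' In the urn task (two urns of three balls, majority colour differing) and
#' in the clinical framing (symptoms versus diagnoses) this probability is
#' 2/3, with equal prior probability for the two states.
#'
#' @param p_signal_given_match Probability of the option-consistent signal
#'   given that option is the true state. Must lie in (0, 1) and differ from
#'   0.5 (an uninformative signal makes inference vacuous).
#' @param prior_A A-priori probability of option A, in (0, 1).
#' @return An object of class `likelihood_spec`.
#' @examples
#' likelihood_spec()            # the 2/3 reliability, equal-prior task
#' likelihood_spec(0.75, 0.5)
#' @export
likelihood_spec <- function(p_signal_given_match = 2 / 3, prior_A = 0.5) {
  stopifnot(is.numeric(p_signal_given_match), length(p_signal_given_match) == 1L,
            is.numeric(prior_A), length(prior_A) == 1L)
  if (p_signal_given_match <= 0 || p_signal_given_match >= 1)
    stop("`p_signal_given_match` must lie strictly between 0 and 1")
  if (p_signal_given_match == 0.5)
    stop("`p_signal_given_match` must differ from 0.5: signals must be informative")
  if (prior_A <= 0 || prior_A >= 1)
    stop("`prior_A` must lie strictly between 0 and 1")
  structure(list(p_signal_given_match = p_signal_given_match, prior_A = prior_A),
            class = "likelihood_spec")
}

#' @export
print.likelihood_spec <- function(x, ...) {
  cat(sprintf("Likelihood spec: p(signal | match) = %.4f, p(A) = %.4f\n",
              x$p_signal_given_match, x$prior_A))
  invisible(x)
}

OPTIONS <- c("A", "B")
SIGNALS <- c("a", "b")
RANKS   <- c("EQ", "HR")  # equally ranked / higher ranked source

#' Construct a sequential decision scenario
#'
#' A scenario describes the situation of the focal (last) decision maker:
#' the ordered public decisions of up to three predecessors, each tagged with
#' the source's hierarchical rank (`"EQ"` for an equally ranked peer, `"HR"`
#' for a higher ranked authority), and the focal actor's own private signal.
#'
#' @param scenario_id Character label identifying the scenario.
#' @param predecessors Character vector of predecessor decisions in order,
#'   each `"A"` or `"B"`; may be empty.
#' @param ranks Character vector of source ranks (`"EQ"`/`"HR"`), recycled if
#'   length one. Defaults to all-`"EQ"`.
#' @param private_signal The focal actor's private signal, `"a"` or `"b"`.
#' @param likelihood A [likelihood_spec()].
#' @param max_predecessors Maximum predecessor count accepted; the task
#'   designs use at most 3 (four sequential decision makers in total), but the
#'   limit can be relaxed.
#' @return An object of class `decision_scenario`.
#' @examples
#' scenario("ex", c("A", "A"), private_signal = "b")
#' @export
scenario <- function(scenario_id, predecessors = character(),
                     ranks = rep("EQ", length(predecessors)),
                     private_signal, likelihood = likelihood_spec(),
                     max_predecessors = 3L) {
  predecessors <- as.character(predecessors)
  if (length(ranks) == 1L) ranks <- rep(ranks, length(predecessors))
  ranks <- as.character(ranks)
  if (!all(predecessors %in% OPTIONS))
    stop("predecessor decisions must be \"A\" or \"B\"")
  if (length(ranks) != length(predecessors))
    stop("`ranks` must match `predecessors` in length")
  if (!all(ranks %in% RANKS))
    stop("ranks must be \"EQ\" or \"HR\"")
  if (length(predecessors) > max_predecessors)
    stop(sprintf("scenario has %d predecessors; at most %d allowed",
                 length(predecessors), max_predecessors))
  if (!(is.character(private_signal) && length(private_signal) == 1L &&
        private_signal %in% SIGNALS))
    stop("`private_signal` must be \"a\" or \"b\"")
  stopifnot(inherits(likelihood, "likelihood_spec"))
  structure(list(scenario_id = as.character(scenario_id),
                 predecessors = predecessors,
                 ranks = ranks,
                 private_signal = private_signal,
                 likelihood = likelihood),
            class = "decision_scenario")
}

#' @export
print.decision_scenario <- function(x, ...) {
  preds <- if (length(x$predecessors) == 0L) "(none)" else
    paste(sprintf("%s:%s", x$ranks, x$predecessors), collapse = "; ")
  cat(sprintf("Scenario %s | predecessors %s | private signal %s\n",
              x$scenario_id, preds, x$private_signal))
  invisible(x)
}

signal_for_option <- function(option) SIGNALS[match(option, OPTIONS)]
option_for_signal <- function(signal) OPTIONS[match(signal, SIGNALS)]

#' Check a scenario for unreasonable predecessor decisions
#'
#' A predecessor's decision is *unreasonable* when it contradicts what a
#' Bayesian decision maker would do under either possible private signal:
#' once the inferred public evidence favours one option by a margin of two or
#' more signals, any rational actor decides for that option regardless of
#' their own draw. A decision against such a margin therefore cannot arise
#' from the assumed decision process, and scenarios containing one are
#' excluded from task designs.
#'
#' @param scenario A [scenario()].
#' @return A list with `valid` (logical) and `reason` (character; empty when
#'   valid, otherwise names the offending predecessor index).
#' @examples
#' validate_scenario(scenario("bad", c("A", "A", "B"), private_signal = "a"))
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "decision_scenario"))
  net <- 0L
  for (i in seq_along(scenario$predecessors)) {
    dec <- scenario$predecessors[i]
    dir <- if (dec == "A") 1L else -1L
    if (abs(net) >= 2L && dir != sign(net)) {
      return(list(valid = FALSE,
                  reason = sprintf(paste0(
                    "predecessor %d decided %s against established public ",
                    "evidence (net signal margin %+d): unreasonable under ",
                    "either private signal"), i, dec, net)))
    }
    if (abs(net) <= 1L) net <- net + dir  # informative decision adds a signal
  }
  list(valid = TRUE, reason = "")
}

#' Infer predecessors' private signals from their public decisions
#'
#' Forward-simulates the public evidence state seen by each predecessor in
#' turn, maintaining the net margin of inferred a- over b-signals. A decision
#' is *informative* — and reveals the decider's private signal exactly —
#' whenever the margin over the already-processed predecessors is at most one
#' in absolute value: at a zero margin the decider follows their own signal
#' (the tie-break assumption), and at a margin of one a decider holding the
#' opposing signal would be at a tie and again follow their own signal, so
#' either way the announced decision matches the private signal. Once the
#' margin reaches two, a decision matching the margin is *uninformative* (a
#' cascade follower decides this way under either signal) and contributes no
#' signal.
#'
#' @param scenario A valid [scenario()].
#' @return An object of class `signal_ledger`: a list with `public`
#'   (data frame of inferred signals and source ranks), `private` (character
#'   vector of private signals), and the totals `n_a`, `n_b`.
#' @examples
#' infer_public_signals(scenario("ex", c("A", "A"), private_signal = "b"))
#' @export
infer_public_signals <- function(scenario) {
  stopifnot(inherits(scenario, "decision_scenario"))
  v <- validate_scenario(scenario)
  if (!v$valid) stop("invalid scenario: ", v$reason)
  net <- 0L
  sig <- character(0)
  rnk <- character(0)
  for (i in seq_along(scenario$predecessors)) {
    dec <- scenario$predecessors[i]
    dir <- if (dec == "A") 1L else -1L
    if (abs(net) <= 1L) {
      # informative: the decision reveals the decider's signal exactly
      sig <- c(sig, signal_for_option(dec))
      rnk <- c(rnk, scenario$ranks[i])
      net <- net + dir
    }
    # |net| >= 2: cascade decision, no signal appended, margin unchanged
  }
  ledger <- list(public = data.frame(signal = sig, rank = rnk,
                                     stringsAsFactors = FALSE),
                 private = scenario$private_signal)
  ledger$n_a <- sum(c(sig, ledger$private) == "a")
  ledger$n_b <- sum(c(sig, ledger$private) == "b")
  class(ledger) <- "signal_ledger"
  ledger
}

#' Build a signal ledger directly from signal counts
#'
#' Convenience constructor used for spot checks and enumeration tests, where
#' the split between public and private signals (and source ranks) either
#' does not matter or is supplied explicitly.
#'
#' @param public Character vector of public signals (`"a"`/`"b"`).
#' @param private Character vector of private signals.
#' @param ranks Ranks of the public signals (recycled; default `"EQ"`).
#' @return A `signal_ledger`.
#' @export
signal_ledger <- function(public = character(), private = character(),
                          ranks = rep("EQ", length(public))) {
  public <- as.character(public); private <- as.character(private)
  if (length(ranks) == 1L) ranks <- rep(ranks, length(public))
  stopifnot(all(public %in% SIGNALS), all(private %in% SIGNALS),
            length(ranks) == length(public), all(ranks %in% RANKS))
  structure(list(public = data.frame(signal = public, rank = as.character(ranks),
                                     stringsAsFactors = FALSE),
                 private = private,
                 n_a = sum(c(public, private) == "a"),
                 n_b = sum(c(public, private) == "b")),
            class = "signal_ledger")
}

#' @export
print.signal_ledger <- function(x, ...) {
  cat(sprintf("Signal ledger: public [%s], private [%s] (n_a = %d, n_b = %d)\n",
              paste(sprintf("%s(%s)", x$public$signal, x$public$rank),
                    collapse = ", "),
              paste(x$private, collapse = ", "), x$n_a, x$n_b))
  invisible(x)
}

#' Per-signal log-likelihood ratio
#'
#' Evaluates `f(x) = ln p(x | A) / p(x | B)` for signals `x`: positive for
#' a-signals, negative for b-signals, symmetric under exchangeable
#' reliabilities.
#'
#' @param signals Character vector of signals (`"a"`/`"b"`).
#' @param spec A [likelihood_spec()].
#' @return Numeric vector of log-likelihood ratios (nats).
#' @export
signal_loglr <- function(signals, spec = likelihood_spec()) {
  stopifnot(inherits(spec, "likelihood_spec"), all(signals %in% SIGNALS))
  p <- spec$p_signal_given_match
  ifelse(signals == "a", log(p / (1 - p)), log((1 - p) / p))
}

#' Posterior log odds of option A from a signal ledger
#'
#' Sums the per-signal log-likelihood ratios over all signals in the ledger
#' and adds the prior log odds. With symmetric reliability `p` and equal
#' priors this reduces to `(n_a - n_b) * ln(p / (1 - p))`: only the signal
#' difference matters, not the absolute counts.
#'
#' @param ledger A `signal_ledger`.
#' @param spec A [likelihood_spec()].
#' @return Natural-log posterior odds of A over B (positive favours A).
#' @examples
#' log_odds(signal_ledger(public = c("a", "a"), private = "b"))  # 0.693
#' @export
log_odds <- function(ledger, spec = likelihood_spec()) {
  stopifnot(inherits(ledger, "signal_ledger"))
  p <- spec$p_signal_given_match
  prior_lo <- log(spec$prior_A / (1 - spec$prior_A))
  prior_lo + (ledger$n_a - ledger$n_b) * log(p / (1 - p))
}

#' Transform log odds to the posterior probability of option A
#'
#' @param l Finite log odds of A over B (nats).
#' @return `1 / (1 + exp(-l))`, the posterior probability of A.
#' @examples
#' posterior_from_log_odds(log(2))      # 0.67 (two-signal margin of one)
#' posterior_from_log_odds(2 * log(2))  # 0.80
#' @export
posterior_from_log_odds <- function(l) {
  stopifnot(is.numeric(l), all(is.finite(l)))
  stats::plogis(l)
}

#' Brute-force Bayesian posterior of option A
#'
#' Evaluates Bayes' theorem directly from the likelihood products
#' `p(n_a, n_b | state)` and the prior, without passing through the log-odds
#' form. Serves as the independent oracle for the
#' [log_odds()] + [posterior_from_log_odds()] pipeline.
#'
#' @param ledger A `signal_ledger`.
#' @param spec A [likelihood_spec()].
#' @return Posterior probability of option A.
#' @export
bayes_posterior_bruteforce <- function(ledger, spec = likelihood_spec()) {
  stopifnot(inherits(ledger, "signal_ledger"))
  p <- spec$p_signal_given_match
  lik_A <- p^ledger$n_a * (1 - p)^ledger$n_b
  lik_B <- (1 - p)^ledger$n_a * p^ledger$n_b
  lik_A * spec$prior_A / (lik_A * spec$prior_A + lik_B * (1 - spec$prior_A))
}

#' Normative Bayesian posterior of a scenario
#'
#' Convenience composition: infer the public signals, accumulate log odds,
#' and transform to the posterior probability of option A.
#'
#' @param scenario A valid [scenario()].
#' @return Posterior probability of option A.
#' @export
scenario_posterior <- function(scenario) {
  posterior_from_log_odds(
    log_odds(infer_public_signals(scenario), scenario$likelihood))
}

#' Mirror a scenario
#'
#' Swaps the two options and the two signals everywhere (A with B, a with b).
#' Mirroring is an involution, and the mirrored scenario's posterior for B
#' equals the original's posterior for A. Task designs present each decision
#' task in both orientations to cancel label preferences.
#'
#' @param scenario A [scenario()].
#' @return The mirrored `decision_scenario`, with `"m"` appended to its id.
#' @export
mirror_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "decision_scenario"))
  flip_opt <- function(x) OPTIONS[3L - match(x, OPTIONS)]
  flip_sig <- function(x) SIGNALS[3L - match(x, SIGNALS)]
  id <- if (endsWith(scenario$scenario_id, "m"))
    sub("m$", "", scenario$scenario_id) else paste0(scenario$scenario_id, "m")
  out <- scenario
  out$scenario_id <- id
  out$predecessors <- if (length(scenario$predecessors))
    flip_opt(scenario$predecessors) else character()
  out$private_signal <- flip_sig(scenario$private_signal)
  out
}
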