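# Scenario-group summaries, printed-table aggregates, authority contrasts,
# and the observed-versus-predicted probability judgment comparison.

#' Classify scenarios by posterior level, evidence relation and authority
#'
#' Derives, for each scenario, the normative posterior level (the Bayesian
#' posterior of the favoured option, rounded to 2 d.p.: 0.50, 0.67, 0.80 or
#' 0.89 in the packaged designs), the relation between the Bayesian
#' prediction and the private signal (`favored` when they agree, `cascade`
#' when the posterior overrides the private signal, `indifference` at 0.50),
#' and the authority condition: `baseline` when no higher ranked source is
#' present, otherwise `supports`/`opposes` according to whether the higher
#' ranked source's decision matches the option favoured by the focal private
#' signal. All labels are derived from the scenario content, never
#' hand-assigned.
#'
#' @param scenarios List of `decision_scenario` objects.
#' @return A data frame with one row per scenario: `scenario_id`,
#'   `posterior_A`, `level`, `bayes_option`, `private_option`, `relation`,
#'   `authority`.
#' @export
classify_scenarios <- function(scenarios) {
  rows <- lapply(scenarios, function(s) {
    pA <- scenario_posterior(s)
    level <- round(max(pA, 1 - pA), 2)
    indiff <- abs(pA - 0.5) < 1e-9
    bayes_option <- if (indiff) NA_character_ else if (pA > 0.5) "A" else "B"
    private_option <- option_for_signal(s$private_signal)
    relation <- if (indiff) "indifference"
      else if (bayes_option == private_option) "favored" else "cascade"
    hr <- which(s$ranks == "HR")
    authority <- if (length(hr) == 0L) "baseline"
      else if (all(s$predecessors[hr] == private_option)) "supports"
      else "opposes"
    data.frame(scenario_id = s$scenario_id, posterior_A = pA, level = level,
               bayes_option = bayes_option, private_option = private_option,
               relation = relation, authority = authority,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-scenario choice-consistency proportions
#'
#' For each scenario, the proportion of recorded choices consistent with the
#' Bayesian-favoured option (`rule = "bayes_consistent"`) or with the option
#' favoured by the participant's private signal
#' (`rule = "private_consistent"`). Bayes-consistency is undefined in
#' indifference scenarios and requesting it there is an error.
#'
#' @param records Records data frame (`participant_id`, `scenario_id`,
#'   `choice`).
#' @param scenarios Named list of scenarios.
#' @param rule Consistency rule.
#' @return Data frame `scenario_id`, `n_choices`, `proportion`.
#' @export
aggregate_choices <- function(records, scenarios,
                              rule = c("bayes_consistent", "private_consistent")) {
  rule <- match.arg(rule)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$scenario_id, character(1))
  missing <- setdiff(unique(records$scenario_id), names(scenarios))
  if (length(missing))
    stop("records reference unknown scenario(s): ", paste(missing, collapse = ", "))
  cls <- classify_scenarios(scenarios)
  used <- cls[cls$scenario_id %in% records$scenario_id, ]
  if (rule == "bayes_consistent" && any(used$relation == "indifference"))
    stop("bayes_consistent is undefined for indifference (0.50) scenarios: ",
         paste(used$scenario_id[used$relation == "indifference"], collapse = ", "))
  target <- if (rule == "bayes_consistent") {
    stats::setNames(used$bayes_option, used$scenario_id)
  } else stats::setNames(used$private_option, used$scenario_id)
  consistent <- records$choice == target[records$scenario_id]
  agg <- stats::aggregate(consistent,
                          by = list(scenario_id = records$scenario_id), mean)
  cnt <- stats::aggregate(consistent,
                          by = list(scenario_id = records$scenario_id), length)
  out <- data.frame(scenario_id = agg$scenario_id, n_choices = cnt$x,
                    proportion = agg$x, stringsAsFactors = FALSE)
  out[match(used$scenario_id, out$scenario_id), , drop = FALSE]
}

#' Scenario-group aggregates from per-scenario percentages
#'
#' Computes the unweighted means of per-scenario choice percentages over the
#' derived scenario groups: all scenarios with a directional Bayesian
#' prediction (`bayes_all`), those where the prediction agrees with the
#' private signal (`bayes_private_favored`), the cascade scenarios where it
#' overrides the private signal (`cascade_bayes`), and the indifference
#' scenarios where the percentage refers to private-signal-consistent
#' choices (`private_indifference`). Group membership is derived via
#' [classify_scenarios()].
#'
#' @param pct Data frame with `scenario_id` and `pct_choice` (percent).
#' @param scenarios Named list of scenarios covering every `scenario_id`.
#' @return Named numeric vector of group means (percent).
#' @export
study_aggregates <- function(pct, scenarios) {
  cls <- classify_scenarios(scenarios)
  m <- merge(cls, pct, by = "scenario_id")
  if (nrow(m) != nrow(pct)) stop("percentages reference unknown scenarios")
  grp_mean <- function(keep) if (any(keep)) mean(m$pct_choice[keep]) else NA_real_
  c(bayes_all = grp_mean(m$relation != "indifference"),
    bayes_private_favored = grp_mean(m$relation == "favored"),
    cascade_bayes = grp_mean(m$relation == "cascade"),
    private_indifference = grp_mean(m$relation == "indifference"))
}

#' Aggregates of the packaged published response tables
#'
#' Applies [study_aggregates()] to the packaged per-scenario response
#' summaries of a study.
#'
#' @param study `"study1"` or `"study2"`.
#' @return Named numeric vector of group means (percent).
#' @export
printed_aggregates <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  study_aggregates(observed_results(study), load_scenarios(study))
}

wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)  # identical behaviour in both conditions
    return(list(z = 0, p = 1, n = 0L, flag = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (V - mu) / sqrt(sigma2) else NA_real_
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        exact = n <= 25)$p.value),
    error = function(e) NA_real_)
  list(z = z, p = p, n = n, flag = if (is.na(z)) "undefined" else "ok")
}

#' Authority-condition contrasts of choices and judgments
#'
#' Within each posterior level, compares the medical-authority conditions
#' against the baseline (no higher ranked source): per participant, the
#' private-signal-consistent choice proportion and the mean probability
#' judgment are computed per condition first, then compared across
#' participants with a Wilcoxon signed-rank test (choices; z from the
#' normal approximation with tie correction, exact p for 25 or fewer
#' non-zero differences) and a paired t test (judgments). Two-sided
#' p-values; degenerate comparisons (all differences zero) are flagged
#' `undefined` rather than reported as significant.
#'
#' @param records Records data frame.
#' @param scenarios Named list of scenarios.
#' @return Data frame with one row per (level, comparison): participant
#'   counts, condition means, Wilcoxon `z`/`p_choice`, and paired-t
#'   `t`/`df`/`p_judgment`.
#' @export
authority_tests <- function(records, scenarios) {
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$scenario_id, character(1))
  cls <- classify_scenarios(scenarios)
  participants <- unique(records$participant_id)
  if (length(participants) < 2L)
    stop("authority tests need at least 2 participants")
  rec <- merge(records, cls, by = "scenario_id")
  rec$private_consistent <- as.numeric(rec$choice == rec$private_option)

  per_part <- function(level, condition, col) {
    sub <- rec[rec$level == level & rec$authority == condition, ]
    m <- tapply(sub[[col]], factor(sub$participant_id, participants), mean)
    as.numeric(m)
  }

  rows <- list()
  for (level in sort(unique(cls$level))) {
    for (cond in c("supports", "opposes")) {
      has <- any(cls$level == level & cls$authority == cond) &&
        any(cls$level == level & cls$authority == "baseline")
      if (!has) next
      ch_base <- per_part(level, "baseline", "private_consistent")
      ch_cond <- per_part(level, cond, "private_consistent")
      jd_base <- per_part(level, "baseline", "judgment")
      jd_cond <- per_part(level, cond, "judgment")
      ok <- stats::complete.cases(ch_base, ch_cond, jd_base, jd_cond)
      w <- wilcoxon_signed_rank(ch_base[ok], ch_cond[ok])
      jd_diff <- jd_base[ok] - jd_cond[ok]
      tt <- if (stats::sd(jd_diff) > 0) {
        h <- stats::t.test(jd_base[ok], jd_cond[ok], paired = TRUE)
        list(t = unname(h$statistic), df = unname(h$parameter),
             p = h$p.value, flag = "ok")
      } else if (all(jd_diff == 0)) {
        list(t = 0, df = sum(ok) - 1, p = 1, flag = "degenerate")
      } else list(t = NA_real_, df = NA_real_, p = NA_real_,
                  flag = "undefined")
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, comparison = paste0("baseline_vs_", cond),
        n_participants = sum(ok),
        choice_baseline = mean(ch_base[ok]), choice_condition = mean(ch_cond[ok]),
        z = w$z, p_choice = w$p, choice_flag = w$flag,
        judgment_baseline = mean(jd_base[ok]),
        judgment_condition = mean(jd_cond[ok]),
        t = tt$t, df = tt$df, p_judgment = tt$p, judgment_flag = tt$flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed versus model-predicted probability judgments by posterior level
#'
#' For each normative posterior level, reports the observed mean judgment
#' (per-scenario means averaged within the level) next to the influence
#' model's predicted judgment under the supplied parameters (typically the
#' group posterior medians of a choice-only fit). Predictions are computed
#' from scenario content and parameters alone — the judgment column is never
#' read on the prediction path — which makes the comparison a generalization
#' test of a model estimated purely from choices.
#'
#' @param records Records data frame (source of the observed judgments).
#' @param params An [influence_params()], e.g. assembled from pooled group
#'   medians.
#' @param scenarios Named list of scenarios.
#' @param judgment_rule Passed to [predict_scenarios()].
#' @return Data frame `level`, `n_scenarios`, `observed`, `predicted`,
#'   `normative`.
#' @export
judgment_comparison <- function(records, params, scenarios,
                                judgment_rule = c("expected", "argmax")) {
  judgment_rule <- match.arg(judgment_rule)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$scenario_id, character(1))
  cls <- classify_scenarios(scenarios)
  pred <- predict_scenarios(scenarios, params, judgment_rule)
  obs <- tapply(records$judgment, records$scenario_id, mean)
  obs_scen <- data.frame(scenario_id = names(obs), judgment = as.numeric(obs),
                         stringsAsFactors = FALSE)
  m <- merge(merge(cls, pred, by = "scenario_id"), obs_scen,
             by = "scenario_id", all.x = TRUE)
  rows <- lapply(sort(unique(m$level)), function(lv) {
    sub <- m[m$level == lv, ]
    data.frame(level = lv, n_scenarios = nrow(sub),
               observed = mean(sub$judgment, na.rm = TRUE),
               predicted = mean(sub$predicted_judgment),
               normative = lv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
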