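# Scenario file I/O and the packaged task-design fixtures.

FIXTURES <- c("study1", "study2")

fixture_path <- function(name) {
  system.file("extdata", sprintf("scenarios_%s.csv", name),
              package = "socialcascade", mustWork = TRUE)
}

parse_predecessor_tokens <- function(tokens, row, relaxed_rank_ok = TRUE) {
  if (is.na(tokens) || !nzchar(trimws(tokens)))
    return(data.frame(rank = character(), decision = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(tokens), ";", fixed = TRUE)[[1]]
  out <- lapply(seq_along(parts), function(j) {
    kv <- strsplit(trimws(parts[j]), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !(kv[1] %in% RANKS) || !(kv[2] %in% OPTIONS))
      stop(sprintf(
        "row %s, field `predecessors`: token %d (%s) is not RANK:DECISION with rank EQ/HR and decision A/B",
        row, j, parts[j]))
    data.frame(rank = kv[1], decision = kv[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

scenario_from_row <- function(df_row, row_label, max_predecessors) {
  for (field in c("scenario_id", "predecessors", "private_signal",
                  "reliability", "prior_A")) {
    if (!field %in% names(df_row))
      stop(sprintf("row %s: missing field `%s`", row_label, field))
  }
  preds <- parse_predecessor_tokens(df_row$predecessors, row_label)
  rel <- suppressWarnings(as.numeric(df_row$reliability))
  pri <- suppressWarnings(as.numeric(df_row$prior_A))
  if (is.na(rel)) stop(sprintf("row %s, field `reliability`: not numeric", row_label))
  if (is.na(pri)) stop(sprintf("row %s, field `prior_A`: not numeric", row_label))
  if (!df_row$private_signal %in% SIGNALS)
    stop(sprintf("row %s, field `private_signal`: must be \"a\" or \"b\"", row_label))
  scenario(scenario_id = df_row$scenario_id,
           predecessors = preds$decision, ranks = preds$rank,
           private_signal = df_row$private_signal,
           likelihood = likelihood_spec(rel, pri),
           max_predecessors = max_predecessors)
}

#' Load decision scenarios from a fixture or file
#'
#' Reads scenario definitions from one of the packaged fixtures (`"study1"`,
#' the 12 urn-task designs; `"study2"`, the 40 clinical-framing designs with
#' mixed source ranks) or from a user-supplied CSV/JSON file following the
#' schema in `inst/extdata/scenario_schema.md`.
#'
#' @param x Fixture name or file path (`.csv` or `.json`).
#' @param mirrored If `TRUE`, append the mirrored presentation of every
#'   scenario (options and signals swapped), as used when each decision task
#'   is shown in both orientations.
#' @param max_predecessors Predecessor-count cap passed to [scenario()];
#'   the packaged designs use at most 3.
#' @return A list of `decision_scenario` objects, named by `scenario_id`.
#' @examples
#' s1 <- load_scenarios("study1")
#' length(load_scenarios("study1", mirrored = TRUE))  # 24
#' @export
load_scenarios <- function(x, mirrored = FALSE, max_predecessors = 3L) {
  path <- if (length(x) == 1L && x %in% FIXTURES) fixture_path(x) else x
  if (!file.exists(path)) stop("no such scenario fixture or file: ", x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    scens <- lapply(seq_along(raw), function(i) {
      rec <- raw[[i]]
      preds <- vapply(rec$predecessors, function(p)
        paste0(p$rank, ":", p$decision), character(1))
      rec$predecessors <- paste(preds, collapse = ";")
      scenario_from_row(rec, as.character(i), max_predecessors)
    })
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    scens <- lapply(seq_len(nrow(df)), function(i)
      scenario_from_row(as.list(df[i, , drop = FALSE]), as.character(i),
                        max_predecessors))
  }
  if (mirrored) scens <- c(scens, lapply(scens, mirror_scenario))
  names(scens) <- vapply(scens, function(s) s$scenario_id, character(1))
  if (anyDuplicated(names(scens)))
    stop("duplicate scenario_id in ", x)
  scens
}

fmt6 <- function(x) formatC(x, format = "g", digits = 6)

#' Write decision scenarios to CSV or JSON
#'
#' Emits byte-stable output for fixed input: fixed column order, sorted JSON
#' keys, and floats formatted with 6 significant digits. Round-trips with
#' [load_scenarios()].
#'
#' @param scenarios List of `decision_scenario` objects.
#' @param path Output path; format chosen by extension (`.json` else CSV).
#' @param study Grouping tag written to the `study` column.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path, study = "custom") {
  stopifnot(all(vapply(scenarios, inherits, logical(1), "decision_scenario")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(scenarios, function(s) {
      list(predecessors = lapply(seq_along(s$predecessors), function(i)
             list(decision = s$predecessors[i], rank = s$ranks[i])),
           prior_A = as.numeric(fmt6(s$likelihood$prior_A)),
           private_signal = s$private_signal,
           reliability = as.numeric(fmt6(s$likelihood$p_signal_given_match)),
           scenario_id = s$scenario_id,
           study = study)
    })
    writeLines(jsonlite::toJSON(unname(recs), auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else {
    df <- data.frame(
      scenario_id = vapply(scenarios, function(s) s$scenario_id, character(1)),
      study = study,
      predecessors = vapply(scenarios, function(s)
        paste(sprintf("%s:%s", s$ranks, s$predecessors), collapse = ";"),
        character(1)),
      private_signal = vapply(scenarios, function(s) s$private_signal,
                              character(1)),
      reliability = fmt6(vapply(scenarios, function(s)
        s$likelihood$p_signal_given_match, numeric(1))),
      prior_A = fmt6(vapply(scenarios, function(s) s$likelihood$prior_A,
                            numeric(1))),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Published per-scenario response summaries
#'
#' Returns the packaged per-scenario response summaries for a study:
#' `pct_choice`, the percentage of choices for the Bayesian-favoured option
#' (for the private-signal-favoured option in indifference scenarios), and
#' `judgment`, the mean probability judgment.
#'
#' @param study `"study1"` or `"study2"`.
#' @return A data frame with columns `scenario_id`, `pct_choice`, `judgment`.
#' @export
observed_results <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  path <- system.file("extdata", sprintf("observed_%s.csv", study),
                      package = "socialcascade", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  df
}

#' Summarise a scenario set as a data frame
#'
#' One row per scenario with its id, predecessor tokens, private signal, and
#' the normative Bayesian posterior for option A.
#'
#' @param scenarios List of `decision_scenario` objects.
#' @return A data frame.
#' @export
scenario_table <- function(scenarios) {
  data.frame(
    scenario_id = vapply(scenarios, function(s) s$scenario_id, character(1)),
    predecessors = vapply(scenarios, function(s)
      paste(sprintf("%s:%s", s$ranks, s$predecessors), collapse = ";"),
      character(1)),
    private_signal = vapply(scenarios, function(s) s$private_signal, character(1)),
    posterior_A = vapply(scenarios, scenario_posterior, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
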