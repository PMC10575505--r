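#' Shipped guideline rule set for outpatient CAP in adults
#'
#' Encodes the first-line oral agents for non-severe community-acquired
#' pneumonia and the permissible average-daily-dose range implied by their
#' recommended regimens:
#'
#' * amoxicillin 1 g two or three times daily — 2000-3000 mg/day;
#' * amoxicillin-clavulanate 875 mg (amoxicillin component) twice daily —
#'   1750 mg/day;
#' * doxycycline 200 mg on day 1 then 100 mg twice daily — collapsed to its
#'   5-day mean of 200 mg/day, since dispensation records carry no
#'   day-by-day schedule.
#'
#' All first-line regimens carry a recommended duration of 5 days.  A
#' relative dose tolerance (default ±10%) widens each bound before
#' concordance is judged, absorbing rounding in strengths and quantities.
#' Common non-first-line agents are included (with `is_first_line = FALSE`
#' and no bounds) so that ATC-based matching can recognise them; the whole
#' rule set can be replaced from YAML via [read_rules()].
#'
#' @param dose_tolerance relative tolerance applied to both dose bounds;
#'   default 0.10.
#' @param duration_tolerance days of slack around the recommended duration
#'   before a duration counts as discordant; default 0 (exact 5 days).
#' @return a tibble with columns `agent`, `atc_code`, `dose_lower_mg_day`,
#'   `dose_upper_mg_day`, `recommended_duration_days`, `is_first_line`, and
#'   attributes `dose_tolerance` / `duration_tolerance`.
#' @export
default_rules <- function(dose_tolerance = 0.10, duration_tolerance = 0) {
  rules <- tibble::tribble(
    ~agent,                      ~atc_code, ~dose_lower_mg_day, ~dose_upper_mg_day, ~recommended_duration_days, ~is_first_line,
    "amoxicillin",               "J01CA04", 2000,               3000,               5,                          TRUE,
    "amoxicillin-clavulanate",   "J01CR02", 1750,               1750,               5,                          TRUE,
    "doxycycline",               "J01AA02", 200,                200,                5,                          TRUE,
    "azithromycin",              "J01FA10", NA,                 NA,                 NA,                         FALSE,
    "clarithromycin",            "J01FA09", NA,                 NA,                 NA,                         FALSE,
    "levofloxacin",              "J01MA12", NA,                 NA,                 NA,                         FALSE,
    "moxifloxacin",              "J01MA14", NA,                 NA,                 NA,                         FALSE,
    "cefuroxime",                "J01DC02", NA,                 NA,                 NA,                         FALSE,
    "cephalexin",                "J01DB01", NA,                 NA,                 NA,                         FALSE,
    "sulfamethoxazole-trimethoprim", "J01EE01", NA,             NA,                 NA,                         FALSE
  )
  validate_rules(rules)
  attr(rules, "dose_tolerance") <- dose_tolerance
  attr(rules, "duration_tolerance") <- duration_tolerance
  rules
}

validate_rules <- function(rules) {
  assert_columns(rules, c("agent", "atc_code", "dose_lower_mg_day", "dose_upper_mg_day",
                          "recommended_duration_days", "is_first_line"), "rule set")
  fl <- rules[rules$is_first_line, , drop = FALSE]
  if (nrow(fl) == 0) stop("rule set has no first-line agent", call. = FALSE)
  bad <- !is.na(fl$dose_lower_mg_day) & !is.na(fl$dose_upper_mg_day) &
    fl$dose_lower_mg_day > fl$dose_upper_mg_day
  if (any(bad)) {
    stop(sprintf("dose_lower > dose_upper for agent(s): %s",
                 paste(fl$agent[bad], collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(fl$dose_lower_mg_day)) || any(is.na(fl$dose_upper_mg_day)) ||
      any(is.na(fl$recommended_duration_days))) {
    stop("first-line agents need dose bounds and a recommended duration", call. = FALSE)
  }
  if (any(fl$recommended_duration_days < 1)) {
    stop("recommended_duration_days must be >= 1", call. = FALSE)
  }
  invisible(rules)
}

#' Read a guideline rule set from YAML
#'
#' The file holds one entry per agent with the fields of the rule table plus
#' optional top-level `dose_tolerance` / `duration_tolerance`.  Validation
#' errors name the offending agent or field.
#'
#' @param path YAML file path.
#' @return a rule tibble as from [default_rules()].
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop(sprintf("rules file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$agents)) stop("rules file must contain an 'agents' list", call. = FALSE)
  rows <- lapply(y$agents, function(a) {
    if (is.null(a$agent)) stop("every rules entry needs an 'agent' name", call. = FALSE)
    tibble::tibble(
      agent = a$agent,
      atc_code = a$atc_code %||% NA_character_,
      dose_lower_mg_day = as.numeric(a$dose_lower_mg_day %||% NA),
      dose_upper_mg_day = as.numeric(a$dose_upper_mg_day %||% NA),
      recommended_duration_days = as.numeric(a$recommended_duration_days %||% NA),
      is_first_line = isTRUE(a$is_first_line)
    )
  })
  rules <- dplyr::bind_rows(rows)
  validate_rules(rules)
  attr(rules, "dose_tolerance") <- as.numeric(y$dose_tolerance %||% 0.10)
  attr(rules, "duration_tolerance") <- as.numeric(y$duration_tolerance %||% 0)
  rules
}

#' Assess guideline concordance of linked prescriptions
#'
#' Matches each prescription to the rule set by ATC code, falling back to the
#' canonical agent name (case-insensitive).  For first-line agents the
#' average daily dose is compared against the tolerance-widened bounds and
#' the duration against the recommended duration; non-first-line agents skip
#' the dose/duration assessment (any dose or duration), so their directions
#' are `NA`.  Agents matching no rule are flagged `unknown_agent` and treated
#' as non-first-line for direction purposes.
#'
#' @param linked output of [link_prescriptions()] restricted to prescribed
#'   rows, or any data frame with `agent`, `atc_code`, `avg_daily_dose_mg`,
#'   `duration_days`.
#' @param rules a rule set from [default_rules()] or [read_rules()].
#' @param dose_tolerance,duration_tolerance overrides for the rule set's
#'   tolerances.
#' @return a tibble aligned with `linked`: `agent_concordant`,
#'   `unknown_agent`, `dose_direction`, `duration_direction` (each one of
#'   `"below"`, `"within"`, `"above"` or `NA`).
#' @export
assess_concordance <- function(linked, rules = default_rules(),
                               dose_tolerance = attr(rules, "dose_tolerance") %||% 0.10,
                               duration_tolerance = attr(rules, "duration_tolerance") %||% 0) {
  assert_columns(linked, c("agent", "atc_code", "avg_daily_dose_mg", "duration_days"),
                 "linked prescriptions")
  n <- nrow(linked)
  idx <- match(as.character(linked$atc_code), rules$atc_code)
  by_name <- match(tolower(as.character(linked$agent)), tolower(rules$agent))
  idx[is.na(idx)] <- by_name[is.na(idx)]
  unknown <- is.na(idx)

  first_line <- !unknown & rules$is_first_line[idx]
  first_line[is.na(first_line)] <- FALSE

  dose_dir <- rep(NA_character_, n)
  dur_dir <- rep(NA_character_, n)
  if (any(first_line)) {
    i <- which(first_line)
    r <- idx[i]
    lo <- rules$dose_lower_mg_day[r] * (1 - dose_tolerance)
    hi <- rules$dose_upper_mg_day[r] * (1 + dose_tolerance)
    dose <- as.numeric(linked$avg_daily_dose_mg[i])
    dose_dir[i] <- ifelse(dose < lo, "below", ifelse(dose > hi, "above", "within"))
    rec <- rules$recommended_duration_days[r]
    dur <- as.numeric(linked$duration_days[i])
    dur_dir[i] <- ifelse(dur < rec - duration_tolerance, "below",
                         ifelse(dur > rec + duration_tolerance, "above", "within"))
  }
  tibble::tibble(
    agent_concordant = first_line,
    unknown_agent = unknown,
    dose_direction = dose_dir,
    duration_direction = dur_dir
  )
}
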