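# Independent brute-force oracles. These are deliberately written with
# different algorithms than the package (pairwise closure, nested loops,
# direct predicates) so agreement is informative.

# episodes as connected components of the "within gap_days" relation over
# sorted visit days (O(n^2) pairwise closure)
oracle_chain <- function(days, gap_days = 14) {
  days <- sort(unique(days))
  n <- length(days)
  if (n == 0) return(list())
  # adjacency between consecutive-in-time points via pairwise distances
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(days[i] - days[j]) <= gap_days && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  unname(split(days, comp))
}

# direct interval scan: which episodes have an admission in
# [index, end + followup]
oracle_hospitalized <- function(episodes, admissions, followup_days = 5) {
  flagged <- character(0)
  for (i in seq_len(nrow(episodes))) {
    for (j in seq_len(nrow(admissions))) {
      if (admissions$patient_id[j] == episodes$patient_id[i] &&
          admissions$admission_date[j] >= episodes$index_date[i] &&
          admissions$admission_date[j] <= episodes$end_date[i] + followup_days) {
        flagged <- c(flagged, episodes$episode_id[i])
        break
      }
    }
  }
  flagged
}

# enumerate every candidate dispensation per episode; earliest date, then
# smallest record id (ignores the overlapping-window rule: use only on
# instances with non-overlapping windows)
oracle_link <- function(episodes, dispensations, followup_days = 5) {
  out <- list()
  for (i in seq_len(nrow(episodes))) {
    if (episodes$excluded[i]) next
    cand <- dispensations[
      dispensations$patient_id == episodes$patient_id[i] &
        startsWith(dispensations$atc_code, "J01") &
        dispensations$dispense_date >= episodes$index_date[i] &
        dispensations$dispense_date <= episodes$end_date[i] + followup_days, ,
      drop = FALSE]
    rid <- if (nrow(cand) == 0) NA_integer_ else {
      cand <- cand[order(cand$dispense_date, cand$record_id), , drop = FALSE]
      cand$record_id[1]
    }
    out[[episodes$episode_id[i]]] <- rid
  }
  out
}

# decision table re-derived directly from the category definitions
oracle_category <- function(first_line, dose_dir, dur_dir, justified, ckd) {
  if (!first_line) {
    return(if (justified) "clinically_appropriate" else "not_recommended")
  }
  any_below <- dose_dir == "below" || dur_dir == "below"
  any_above <- dose_dir == "above" || dur_dir == "above"
  if (any_below) {
    return(if (ckd) "clinically_appropriate" else "undertreatment")
  }
  if (any_above) return("effective_but_unnecessary")
  "guideline_adherent"
}

make_visits <- function(days, patient_id = "p1", code = "481", system = "ICD9",
                        origin = as.Date("2014-01-01")) {
  tibble::tibble(
    patient_id = patient_id,
    service_date = origin + days,
    diagnostic_code = code,
    code_system = system,
    provider_type = "GP"
  )
}

make_dispensation <- function(record_id, patient_id, date,
                              agent = "amoxicillin", atc = "J01CA04",
                              strength = 500, quantity = 20, days_supply = 5) {
  tibble::tibble(
    record_id = record_id, patient_id = patient_id,
    dispense_date = as.Date(date), agent = agent, atc_code = atc,
    strength_mg = strength, quantity = quantity, days_supply = days_supply,
    form = "tablet"
  )
}

# a minimal one-row justification profile for classifier tests
make_justification <- function(episode_id, justified = FALSE, ckd = FALSE) {
  tibble::tibble(
    episode_id = episode_id,
    chronic_kidney_disease = ckd,
    has_any_justification = justified | ckd
  )
}
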