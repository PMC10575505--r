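#' Build acute episodes of infection from CAP visit claims
#'
#' Chains each patient's CAP-coded physician visits into episodes of care.
#' Under the default `rolling` semantics a visit joins the current episode
#' when it falls within `gap_days` of the *previous* visit; under
#' `from_index` it must fall within `gap_days` of the episode's first visit.
#' The index date is the first visit of the chain.  Episodes whose total span
#' exceeds `max_span_days` are flagged `chronic_span` but never dropped, so
#' exclusion counts remain reportable.
#'
#' @param cap_visits data frame with columns `patient_id`, `service_date`
#'   (Date or ISO string); typically the output of [identify_cap_visits()].
#' @param gap_days maximum inter-visit gap (days) for two visits to share an
#'   episode; default 14.
#' @param max_span_days maximum total span (last minus first visit, days) for
#'   an acute episode; spans strictly greater are flagged chronic.  Default
#'   30 (a 30-day span is kept, 31 is excluded).
#' @param gap_semantics `"rolling"` (default) or `"from_index"`.
#' @return a tibble with one row per episode: `episode_id`, `patient_id`,
#'   `index_date`, `end_date`, `span_days`, `n_visits`, `visit_dates`
#'   (list column), `excluded`, `exclusion_reason`.
#' @export
#' @examples
#' v <- tibble::tibble(patient_id = "p1",
#'                     service_date = as.Date("2014-01-01") + c(0, 10, 22))
#' build_episodes(v)  # one episode, span 22
build_episodes <- function(cap_visits, gap_days = 14, max_span_days = 30,
                           gap_semantics = c("rolling", "from_index")) {
  gap_semantics <- match.arg(gap_semantics)
  assert_columns(cap_visits, c("patient_id", "service_date"), "cap_visits")
  empty <- tibble::tibble(
    episode_id = character(0), patient_id = character(0),
    index_date = as.Date(character(0)), end_date = as.Date(character(0)),
    span_days = integer(0), n_visits = integer(0),
    visit_dates = list(), excluded = logical(0), exclusion_reason = character(0)
  )
  if (nrow(cap_visits) == 0) return(empty)

  v <- tibble::tibble(
    patient_id = as.character(cap_visits$patient_id),
    service_date = as.Date(cap_visits$service_date)
  )
  v <- dplyr::arrange(v, .data$patient_id, .data$service_date)
  v <- dplyr::distinct(v)   # duplicate same-day claims collapse to one visit

  # chain within patient: new episode when the gap criterion fails
  d <- as.numeric(v$service_date)
  new_patient <- c(TRUE, v$patient_id[-1] != v$patient_id[-nrow(v)])
  if (gap_semantics == "rolling") {
    gap <- c(Inf, diff(d))
    gap[new_patient] <- Inf
    new_episode <- new_patient | gap > gap_days
    chain <- cumsum(new_episode)
  } else {
    # from_index needs a scan: anchor resets when distance from it exceeds gap
    chain <- integer(nrow(v))
    cid <- 0L
    anchor <- -Inf
    for (i in seq_len(nrow(v))) {
      if (new_patient[i] || d[i] - anchor > gap_days) {
        cid <- cid + 1L
        anchor <- d[i]
      }
      chain[i] <- cid
    }
  }
  v$chain <- if (gap_semantics == "rolling") chain else chain

  ep <- dplyr::summarise(
    dplyr::group_by(v, .data$patient_id, .data$chain),
    index_date = min(.data$service_date),
    end_date = max(.data$service_date),
    n_visits = dplyr::n(),
    visit_dates = list(.data$service_date),
    .groups = "drop"
  )
  ep <- dplyr::arrange(ep, .data$patient_id, .data$index_date)
  seq_in_patient <- stats::ave(seq_len(nrow(ep)), ep$patient_id, FUN = seq_along)
  ep$episode_id <- sprintf("%s-E%03d", ep$patient_id, seq_in_patient)
  ep$span_days <- days_between(ep$index_date, ep$end_date)
  ep$exclusion_reason <- ifelse(ep$span_days > max_span_days, "chronic_span", "none")
  ep$excluded <- ep$exclusion_reason != "none"
  ep[, c("episode_id", "patient_id", "index_date", "end_date", "span_days",
         "n_visits", "visit_dates", "excluded", "exclusion_reason")]
}

#' Flag episodes followed by a hospital admission
#'
#' An episode is presumed to have been treated as an inpatient — and is
#' therefore excluded from the outpatient prescribing analysis — when the
#' patient has a hospital admission between the episode index date and
#' `followup_days` after the final visit, endpoints inclusive.  Episodes
#' already excluded (chronic span) keep their original reason; flagging is
#' idempotent.
#'
#' @param episodes output of [build_episodes()].
#' @param admissions data frame with columns `patient_id`, `admission_date`.
#' @param followup_days days after the episode end still counted as an
#'   episode-attributable admission; default 5.
#' @return `episodes` with updated `excluded` / `exclusion_reason`.
#' @export
exclude_hospitalized <- function(episodes, admissions, followup_days = 5) {
  if (nrow(episodes) == 0) return(episodes)
  if (is.null(admissions) || nrow(admissions) == 0) return(episodes)
  assert_columns(admissions, c("patient_id", "admission_date"), "admissions")
  adm <- tibble::tibble(
    patient_id = as.character(admissions$patient_id),
    admission_date = as.Date(admissions$admission_date)
  )
  cand <- dplyr::inner_join(
    episodes[, c("episode_id", "patient_id", "index_date", "end_date")],
    adm, by = "patient_id", relationship = "many-to-many"
  )
  hit <- cand$admission_date >= cand$index_date &
    cand$admission_date <= cand$end_date + followup_days
  flagged <- unique(cand$episode_id[hit])
  mark <- episodes$episode_id %in% flagged & episodes$exclusion_reason == "none"
  episodes$exclusion_reason[mark] <- "hospitalized"
  episodes$excluded <- episodes$exclusion_reason != "none"
  episodes
}
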