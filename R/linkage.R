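#' Average daily dose of a dispensation
#'
#' Total dispensed drug mass divided by days supply, in mg/day.  For
#' combination products (amoxicillin-clavulanate) `strength_mg` is by
#' convention the amoxicillin-component strength per unit, so the daily dose
#' is on the same scale as the guideline bounds.
#'
#' @param strength_mg mg of active component per unit dispensed.
#' @param quantity units dispensed.
#' @param days_supply days the dispensation is intended to cover.
#' @return mg/day, vectorised.
#' @export
#' @examples
#' average_daily_dose(500, 30, 10)  # 1500 mg/day
average_daily_dose <- function(strength_mg, quantity, days_supply) {
  if (any(!is.finite(days_supply) | days_supply <= 0)) {
    stop("days_supply must be positive for every dispensation record", call. = FALSE)
  }
  if (any(!is.finite(strength_mg) | strength_mg <= 0) ||
      any(!is.finite(quantity) | quantity <= 0)) {
    stop("strength_mg and quantity must be positive", call. = FALSE)
  }
  strength_mg * quantity / days_supply
}

#' Link the first antibiotic dispensation to each episode
#'
#' For every non-excluded episode, candidate dispensations are those of the
#' same patient, restricted to systemic antibacterials (ATC prefix `J01` by
#' default), dispensed between the episode index date and `followup_days`
#' after the final visit (inclusive).  Only the earliest candidate is kept —
#' empiric therapy is judged on the first dispensation — with ties on date
#' broken by smallest `record_id`.  A dispensation eligible for two episodes
#' of the same patient (overlapping windows) is assigned to the episode with
#' the later index date, with a warning.  Episodes with no candidate are
#' returned as unprescribed rows.
#'
#' @param episodes output of [build_episodes()] (after
#'   [exclude_hospitalized()]); excluded episodes are not linked.
#' @param dispensations data frame with columns `record_id`, `patient_id`,
#'   `dispense_date`, `agent`, `atc_code`, `strength_mg`, `quantity`,
#'   `days_supply`.
#' @param followup_days linkage follow-up after the final visit; default 5.
#' @param atc_include ATC prefix defining antibacterials; default `"J01"`.
#' @return a tibble with one row per kept episode: episode keys, `prescribed`,
#'   and for prescribed episodes the linked record's fields plus
#'   `avg_daily_dose_mg`, `duration_days` (= days supply) and
#'   `dispense_offset` (days from index).
#' @export
link_prescriptions <- function(episodes, dispensations, followup_days = 5,
                               atc_include = "J01") {
  kept <- episodes[!episodes$excluded, , drop = FALSE]
  base <- tibble::tibble(
    episode_id = kept$episode_id,
    patient_id = kept$patient_id,
    index_date = kept$index_date,
    end_date = kept$end_date
  )
  rx_cols <- c("record_id", "agent", "atc_code", "strength_mg", "quantity",
               "days_supply", "avg_daily_dose_mg", "duration_days", "dispense_offset")
  if (nrow(kept) == 0) {
    out <- base
    out$prescribed <- logical(0)
    for (cl in rx_cols) out[[cl]] <- if (cl %in% c("agent", "atc_code")) character(0) else numeric(0)
    return(out)
  }

  dsp <- dispensations
  if (!is.null(dsp) && nrow(dsp) > 0) {
    assert_columns(dsp, c("record_id", "patient_id", "dispense_date", "agent",
                          "atc_code", "strength_mg", "quantity", "days_supply"),
                   "dispensations")
    dsp <- dsp[startsWith(as.character(dsp$atc_code), atc_include), , drop = FALSE]
  }
  if (is.null(dsp) || nrow(dsp) == 0) {
    out <- base
    out$prescribed <- FALSE
    out$record_id <- NA_real_
    out$agent <- NA_character_
    out$atc_code <- NA_character_
    out$strength_mg <- NA_real_
    out$quantity <- NA_real_
    out$days_supply <- NA_real_
    out$avg_daily_dose_mg <- NA_real_
    out$duration_days <- NA_real_
    out$dispense_offset <- NA_real_
    return(out)
  }
  dsp <- tibble::tibble(
    record_id = dsp$record_id,
    patient_id = as.character(dsp$patient_id),
    dispense_date = as.Date(dsp$dispense_date),
    agent = as.character(dsp$agent),
    atc_code = as.character(dsp$atc_code),
    strength_mg = as.numeric(dsp$strength_mg),
    quantity = as.numeric(dsp$quantity),
    days_supply = as.numeric(dsp$days_supply)
  )

  cand <- dplyr::inner_join(base, dsp, by = "patient_id",
                            relationship = "many-to-many")
  cand <- cand[cand$dispense_date >= cand$index_date &
                 cand$dispense_date <= cand$end_date + followup_days, , drop = FALSE]

  linked <- base["episode_id"]
  if (nrow(cand) > 0) {
    # a record reachable from two episode windows goes to the later index
    n_per_record <- table(cand$record_id)
    if (any(n_per_record > 1)) {
      warning(sprintf(
        "%d dispensation record(s) fell inside overlapping episode windows; assigned to the later episode",
        sum(n_per_record > 1)), call. = FALSE)
      cand <- dplyr::arrange(cand, .data$record_id, dplyr::desc(.data$index_date))
      cand <- cand[!duplicated(cand$record_id), , drop = FALSE]
    }
    cand <- dplyr::arrange(cand, .data$episode_id, .data$dispense_date, .data$record_id)
    first <- cand[!duplicated(cand$episode_id), , drop = FALSE]
    first$avg_daily_dose_mg <- average_daily_dose(first$strength_mg, first$quantity,
                                                  first$days_supply)
    first$duration_days <- first$days_supply
    first$dispense_offset <- days_between(first$index_date, first$dispense_date)
    linked <- first[, c("episode_id", "record_id", "agent", "atc_code", "strength_mg",
                        "quantity", "days_supply", "avg_daily_dose_mg",
                        "duration_days", "dispense_offset")]
  }
  out <- dplyr::left_join(base, linked, by = "episode_id")
  if (!"record_id" %in% names(out)) {  # no candidates at all
    out$record_id <- NA_real_
  }
  out$prescribed <- !is.na(out$record_id)
  missing_cols <- setdiff(rx_cols, names(out))
  for (cl in missing_cols) out[[cl]] <- if (cl %in% c("agent", "atc_code")) NA_character_ else NA_real_
  out[, c("episode_id", "patient_id", "index_date", "end_date", "prescribed", rx_cols)]
}

#' Suppress small cells in a count table
#'
#' Privacy suppression for reporting: every count below `min_n` is replaced by
#' a marker string, and any derived columns (percentages, rates) computed from
#' a suppressed count are suppressed with it.  Count columns are returned as
#' character so the marker and retained values coexist; the operation is
#' idempotent.
#'
#' @param table a data frame of counts, or an atomic numeric vector/matrix.
#' @param count_col name of the count column (data-frame input); default `"n"`.
#' @param derived_cols character vector of columns derived from the count, to
#'   be suppressed alongside it.
#' @param min_n smallest reportable count; default 6 (counts of 1-5 masked).
#' @param marker suppression marker; default `"<6"`.
#' @return same shape as the input with suppressed cells replaced by `marker`.
#' @export
#' @examples
#' suppress_small_cells(c(3, 6, 12))
suppress_small_cells <- function(table, count_col = "n", derived_cols = character(0),
                                 min_n = 6, marker = "<6") {
  if (is.atomic(table) && !is.data.frame(table)) {
    out <- as.character(table)
    val <- suppressWarnings(as.numeric(out))
    out[!is.na(val) & val < min_n] <- marker
    if (is.matrix(table)) dim(out) <- dim(table)
    return(out)
  }
  assert_columns(table, count_col, "count table")
  cnt <- as.character(table[[count_col]])
  val <- suppressWarnings(as.numeric(cnt))
  hide <- (!is.na(val) & val < min_n) | cnt == marker
  cnt[hide] <- marker
  table[[count_col]] <- cnt
  for (dc in intersect(derived_cols, names(table))) {
    dv <- as.character(table[[dc]])
    dv[hide] <- marker
    table[[dc]] <- dv
  }
  table
}
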