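#' Classic Charlson comorbidity weights for the shipped condition registry
#'
#' Weights follow the classic Charlson index: myocardial infarction,
#' congestive heart failure, chronic pulmonary disease (COPD and asthma) and
#' diabetes weigh 1; any malignancy and renal disease weigh 2.  Coronary
#' artery disease and hypertension are tracked as prescribing justifications
#' but are not Charlson conditions, so they carry weight 0.  The table is
#' configuration: validated claims implementations use institution-specific
#' variants, which can be supplied in its place.
#'
#' @return named integer vector, one entry per configured condition.
#' @export
default_charlson_weights <- function() {
  c(
    myocardial_infarction = 1L,
    congestive_heart_failure = 1L,
    copd = 1L,
    asthma = 1L,
    diabetes = 1L,
    cancer = 2L,
    chronic_kidney_disease = 2L,
    coronary_artery_disease = 0L,
    hypertension = 0L
  )
}

#' Charlson comorbidity score from condition flags
#'
#' @param condition_flags named logical vector (or a data frame of logical
#'   columns, scored row-wise) of present conditions.
#' @param weight_table named integer vector of weights; every flagged
#'   condition must appear in it.
#' @return integer score(s): the sum of weights over present conditions.
#' @export
#' @examples
#' compute_charlson(c(myocardial_infarction = TRUE, diabetes = TRUE, cancer = TRUE))
compute_charlson <- function(condition_flags, weight_table = default_charlson_weights()) {
  if (is.data.frame(condition_flags)) {
    conds <- names(condition_flags)
    missing <- setdiff(conds, names(weight_table))
    if (length(missing) > 0) {
      stop(sprintf("condition(s) absent from Charlson weight table: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    m <- as.matrix(condition_flags) * 1
    return(as.integer(m %*% weight_table[conds]))
  }
  conds <- names(condition_flags)
  if (is.null(conds)) stop("condition_flags must be named", call. = FALSE)
  missing <- setdiff(conds, names(weight_table))
  if (length(missing) > 0) {
    stop(sprintf("condition(s) absent from Charlson weight table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.integer(sum(weight_table[conds][condition_flags]))
}

#' Build per-episode clinical justification profiles
#'
#' Scans each episode's lookback window `[index_date - lookback_days,
#' index_date]` for evidence of the configured comorbidities and medication
#' classes:
#'
#' * outpatient visit claims, matched by diagnosis-code prefix per tagged
#'   system (ICD-9 / OHIP);
#' * hospital admissions, matched against ICD-10 diagnosis codes (the
#'   `diagnosis_codes` field may be a list column or `;`-separated strings);
#' * dispensation records, matched by ATC prefix for the medication classes
#'   (immunosuppressants, agents with moderate/severe interactions against
#'   first-line CAP antibiotics).
#'
#' The Charlson score is computed from the condition flags with
#' `charlson_weights`; `has_any_justification` is true when any condition or
#' medication flag is set or the Charlson score reaches
#' `charlson_threshold` (moderate/severe).
#'
#' @param episodes data frame with `episode_id`, `patient_id`, `index_date`.
#' @param visits,admissions,dispensations claims tables (any may be `NULL`).
#' @param code_config code configuration, see [default_code_config()].
#' @param lookback_days days before index searched for evidence; default 365.
#'   May be a single value or a named vector of per-condition overrides with
#'   a `.default` entry.
#' @param charlson_weights named weight vector; default
#'   [default_charlson_weights()].
#' @param charlson_threshold score at which the index alone justifies
#'   non-first-line therapy; default 3.
#' @return tibble: `episode_id`, one logical column per condition, logical
#'   `interacting_drugs` and `immunosuppressive_meds`, `charlson_score`,
#'   `charlson_moderate_severe`, `has_any_justification`.
#' @export
build_justification_table <- function(episodes, visits = NULL, admissions = NULL,
                                      dispensations = NULL,
                                      code_config = default_code_config(),
                                      lookback_days = 365,
                                      charlson_weights = default_charlson_weights(),
                                      charlson_threshold = 3) {
  assert_columns(episodes, c("episode_id", "patient_id", "index_date"), "episodes")
  code_config <- validate_code_config(code_config)
  conds <- names(code_config$conditions)
  med_classes <- names(code_config$medication_classes)
  missing_w <- setdiff(conds, names(charlson_weights))
  if (length(missing_w) > 0) {
    stop(sprintf("condition(s) absent from Charlson weight table: %s",
                 paste(missing_w, collapse = ", ")), call. = FALSE)
  }

  lb_for <- function(cond) {
    if (length(lookback_days) == 1 && is.null(names(lookback_days))) return(as.numeric(lookback_days))
    as.numeric(lookback_days[[cond]] %||% lookback_days[[".default"]] %||% 365)
  }

  out <- tibble::tibble(
    episode_id = episodes$episode_id,
    patient_id = as.character(episodes$patient_id),
    index_date = as.Date(episodes$index_date)
  )

  # assemble one long table of dated, system-tagged diagnosis events
  diag_events <- list()
  if (!is.null(visits) && nrow(visits) > 0) {
    diag_events$visits <- tibble::tibble(
      patient_id = as.character(visits$patient_id),
      date = as.Date(visits$service_date),
      code = trimws(as.character(visits$diagnostic_code)),
      system = as.character(visits$code_system)
    )
  }
  if (!is.null(admissions) && nrow(admissions) > 0) {
    codes <- admissions$diagnosis_codes
    if (!is.list(codes)) codes <- strsplit(as.character(codes), ";", fixed = TRUE)
    lens <- lengths(codes)
    diag_events$admissions <- tibble::tibble(
      patient_id = rep(as.character(admissions$patient_id), lens),
      date = rep(as.Date(admissions$admission_date), lens),
      code = trimws(unlist(codes, use.names = FALSE)),
      system = "ICD10"
    )
  }
  diag <- dplyr::bind_rows(diag_events)

  flag_events <- function(ev, cond) {
    # episodes with >=1 matching event inside the condition's lookback window
    if (is.null(ev) || nrow(ev) == 0) return(character(0))
    hits <- dplyr::inner_join(out[, c("episode_id", "patient_id", "index_date")],
                              ev, by = "patient_id", relationship = "many-to-many")
    lb <- lb_for(cond)
    hits <- hits[hits$date <= hits$index_date &
                   hits$date >= hits$index_date - lb, , drop = FALSE]
    unique(hits$episode_id)
  }

  for (cond in conds) {
    cfg <- code_config$conditions[[cond]]
    matched <- NULL
    if (!is.null(diag) && nrow(diag) > 0) {
      keep <- logical(nrow(diag))
      for (sys in unique(diag$system)) {
        pref <- condition_prefixes(cfg, sys)
        i <- diag$system == sys
        keep[i] <- matches_any_prefix(diag$code[i], pref)
      }
      matched <- diag[keep, , drop = FALSE]
    }
    out[[cond]] <- out$episode_id %in% flag_events(matched, cond)
  }

  med_events <- NULL
  if (!is.null(dispensations) && nrow(dispensations) > 0) {
    med_events <- tibble::tibble(
      patient_id = as.character(dispensations$patient_id),
      date = as.Date(dispensations$dispense_date),
      code = trimws(as.character(dispensations$atc_code))
    )
  }
  for (mc in med_classes) {
    pref <- code_config$medication_classes[[mc]]$ATC
    matched <- NULL
    if (!is.null(med_events)) {
      matched <- med_events[matches_any_prefix(med_events$code, pref), , drop = FALSE]
    }
    out[[mc]] <- out$episode_id %in% flag_events(matched, mc)
  }

  out$charlson_score <- compute_charlson(out[, conds, drop = FALSE], charlson_weights)
  out$charlson_moderate_severe <- out$charlson_score >= charlson_threshold
  med_any <- Reduce(`|`, lapply(med_classes, function(mc) out[[mc]]), init = logical(nrow(out)))
  cond_any <- Reduce(`|`, lapply(conds, function(cc) out[[cc]]), init = logical(nrow(out)))
  out$has_any_justification <- cond_any | med_any | out$charlson_moderate_severe
  out[, c("episode_id", conds, med_classes, "charlson_score",
          "charlson_moderate_severe", "has_any_justification")]
}

#' Justification profile for a single episode
#'
#' Convenience wrapper around [build_justification_table()] for one patient
#' and index date.
#'
#' @param patient_id patient identifier.
#' @param index_date episode index date.
#' @inheritParams build_justification_table
#' @return a one-row tibble, see [build_justification_table()].
#' @export
build_justifications <- function(patient_id, index_date, visits = NULL,
                                 admissions = NULL, dispensations = NULL,
                                 code_config = default_code_config(),
                                 lookback_days = 365,
                                 charlson_weights = default_charlson_weights(),
                                 charlson_threshold = 3) {
  ep <- tibble::tibble(episode_id = "episode-1", patient_id = as.character(patient_id),
                       index_date = as.Date(index_date))
  build_justification_table(ep, visits, admissions, dispensations, code_config,
                            lookback_days, charlson_weights, charlson_threshold)
}

quality_categories <- function() {
  c("guideline_adherent", "clinically_appropriate", "effective_but_unnecessary",
    "undertreatment", "not_recommended")
}

#' Classify one prescription into a quality category
#'
#' The ordered decision table over agent class, dose/duration directions and
#' patient justifications:
#'
#' 1. non-first-line agent with at least one justification — clinically
#'    appropriate;
#' 2. non-first-line agent with no justification — not recommended;
#' 3. first-line agent, dose and duration both within bounds — guideline
#'    adherent;
#' 4. first-line agent with any subtherapeutic axis — undertreatment (a
#'    "below" on either axis dominates, which also settles opposing-direction
#'    conflicts in favour of undertreatment);
#' 5. first-line agent with an excessive axis and none below — effective but
#'    unnecessary.
#'
#' Finally an undertreatment call in the presence of chronic kidney disease
#' is reclassified as clinically appropriate, consistent with renal dosing
#' adjustments when creatinine clearance is unobserved.
#'
#' @param first_line is the agent first-line?
#' @param dose_direction,duration_direction `"below"`/`"within"`/`"above"`
#'   (ignored for non-first-line agents).
#' @param has_any_justification any clinical justification present?
#' @param ckd chronic kidney disease flag.
#' @param unknown_agent agent matched no rule; resolved per
#'   `unknown_agent_policy`.
#' @param unknown_agent_policy `"non_first_line"` (default) or `"error"`.
#' @return list with `category`, `reclassified_from_undertreatment`,
#'   `reason_trace` (semicolon-joined rule ids).
#' @export
classify_one <- function(first_line, dose_direction, duration_direction,
                         has_any_justification, ckd, unknown_agent = FALSE,
                         unknown_agent_policy = c("non_first_line", "error")) {
  unknown_agent_policy <- match.arg(unknown_agent_policy)
  trace <- character(0)
  if (isTRUE(unknown_agent)) {
    if (unknown_agent_policy == "error") stop("unknown agent", call. = FALSE)
    first_line <- FALSE
    trace <- c(trace, "unknown_agent_as_non_first_line")
  }
  if (!first_line) {
    if (has_any_justification) {
      return(list(category = "clinically_appropriate",
                  reclassified_from_undertreatment = FALSE,
                  reason_trace = paste(c(trace, "R1:non_first_line_justified"), collapse = ";")))
    }
    return(list(category = "not_recommended",
                reclassified_from_undertreatment = FALSE,
                reason_trace = paste(c(trace, "R2:non_first_line_unjustified"), collapse = ";")))
  }
  if (dose_direction == "within" && duration_direction == "within") {
    return(list(category = "guideline_adherent",
                reclassified_from_undertreatment = FALSE,
                reason_trace = paste(c(trace, "R3:first_line_fully_concordant"), collapse = ";")))
  }
  if (dose_direction == "below" || duration_direction == "below") {
    if (isTRUE(ckd)) {
      return(list(category = "clinically_appropriate",
                  reclassified_from_undertreatment = TRUE,
                  reason_trace = paste(c(trace, "R4:subtherapeutic_axis",
                                         "R6:ckd_reclassification"), collapse = ";")))
    }
    return(list(category = "undertreatment",
                reclassified_from_undertreatment = FALSE,
                reason_trace = paste(c(trace, "R4:subtherapeutic_axis"), collapse = ";")))
  }
  list(category = "effective_but_unnecessary",
       reclassified_from_undertreatment = FALSE,
       reason_trace = paste(c(trace, "R5:excessive_axis"), collapse = ";"))
}

#' Classify linked prescriptions (vectorised)
#'
#' Joins concordance results and justification profiles to the prescribed
#' rows of the linked table and applies the decision table of
#' [classify_one()] to every prescription.
#'
#' @param linked output of [link_prescriptions()]; only `prescribed` rows are
#'   classified.
#' @param concordance output of [assess_concordance()] on those rows (built
#'   internally when `NULL`).
#' @param justifications output of [build_justification_table()], joined by
#'   `episode_id`.
#' @param rules rule set, used when `concordance` is `NULL`.
#' @param ckd_condition name of the renal-dysfunction flag used for the
#'   undertreatment reclassification; default `"chronic_kidney_disease"`.
#' @param unknown_agent_policy see [classify_one()].
#' @return the prescribed rows of `linked` with `category`,
#'   `reclassified_from_undertreatment`, `reason_trace`, the concordance
#'   columns and `has_any_justification` attached.
#' @export
classify_prescriptions <- function(linked, justifications, concordance = NULL,
                                   rules = default_rules(),
                                   ckd_condition = "chronic_kidney_disease",
                                   unknown_agent_policy = "non_first_line") {
  rx <- linked[linked$prescribed %||% rep(TRUE, nrow(linked)), , drop = FALSE]
  if (is.null(concordance)) concordance <- assess_concordance(rx, rules)
  stopifnot(nrow(concordance) == nrow(rx))
  rx <- dplyr::bind_cols(rx, concordance)
  just_cols <- c("episode_id", ckd_condition, "has_any_justification")
  assert_columns(justifications, just_cols, "justifications")
  rx <- dplyr::left_join(rx, justifications, by = "episode_id")
  if (anyNA(rx$has_any_justification)) {
    stop("every prescribed episode needs a justification profile", call. = FALSE)
  }

  n <- nrow(rx)
  category <- character(n)
  reclass <- logical(n)
  trace <- character(n)
  for (i in seq_len(n)) {
    res <- classify_one(
      first_line = rx$agent_concordant[i],
      dose_direction = rx$dose_direction[i],
      duration_direction = rx$duration_direction[i],
      has_any_justification = rx$has_any_justification[i],
      ckd = rx[[ckd_condition]][i],
      unknown_agent = rx$unknown_agent[i],
      unknown_agent_policy = unknown_agent_policy
    )
    category[i] <- res$category
    reclass[i] <- res$reclassified_from_undertreatment
    trace[i] <- res$reason_trace
  }
  rx$category <- factor(category, levels = quality_categories())
  rx$reclassified_from_undertreatment <- reclass
  rx$reason_trace <- trace
  rx
}
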