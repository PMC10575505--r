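#' Configuration for the synthetic claims generator
#'
#' Bundles every knob of the generator with defaults calibrated to the
#' published provincial cohort this package models: a senior (65+) outpatient
#' CAP cohort with age 77.98 +/- 8.37, 53.3% female, roughly 46-52% of
#' episodes prescribed an antibiotic, a modal dispensed duration of 7 days
#' (then 10, then 5), an average of ~1.7 physician visits per episode, and
#' the comorbidity prevalences of the published cohort table.
#'
#' The per-prescription quality-category mix is a *target*: categories are
#' drawn from `category_mix` restricted to those feasible for the patient's
#' justification state (a not-recommended prescription requires a patient
#' with no justification; a clinically-appropriate one requires at least
#' one), renormalised.  An undertreatment draw for a chronic-kidney-disease
#' patient yields an intended clinically-appropriate (reclassified) label.
#'
#' Dates are integer day offsets from `epoch`, serialised ISO-8601.  Patient
#' episodes are placed in equal blocks of the study window at least 65 days
#' apart so that episode windows, decoy dispensations and hospitalisation
#' windows can never interact across episodes — this is what makes the
#' generated ground truth exact.
#'
#' @param seed master seed; every table draws from its own stream derived
#'   from it.
#' @param n_patients cohort size.
#' @param years inclusive study years.
#' @param epoch day-offset origin (ISO date string).
#' @param provinces named probability vector of province labels.
#' @param age_mean,age_sd,age_min truncated-normal age model (minimum 65).
#' @param prop_female probability a patient is female.
#' @param ltc_fraction fraction flagged as long-term-care residents (an
#'   exclusion the pipeline must apply).
#' @param comorbidity_prevalence named condition -> probability map.
#' @param medication_prevalence named map for `interacting_drugs` and
#'   `immunosuppressive_meds`.
#' @param episodes_per_patient_lambda episodes per patient are
#'   `1 + Poisson(lambda)`, capped at 8.
#' @param visit_pmf pmf over visits per episode (names = counts).
#' @param prescribe_probability per-episode probability an antibiotic is
#'   dispensed.
#' @param category_mix named target mix over the five quality categories
#'   (sums to 1).
#' @param duration_pmf pmf over dispensed durations for non-first-line
#'   agents (names = days, support within 1..30).
#' @param hospitalization_probability per-episode probability of an
#'   admission starting within 5 days of the episode end.
#' @param chronic_rate fraction of episodes deliberately generated with a
#'   span over 30 days (to exercise the chronic exclusion).
#' @param decoy_rate fraction of prescribed episodes that also receive a
#'   decoy dispensation (second-in-window, or just outside the window) to
#'   exercise the first-dispensation rule.
#' @param edge_case_rate fraction of prescribed episodes given a
#'   deliberately unclassifiable prescription (agent outside the rule set,
#'   intended category unknown); default 0.
#' @return a validated `cap_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 10000L,
                       years = 2014:2018,
                       epoch = "2014-01-01",
                       provinces = c(BC = 0.27, ON = 0.73),
                       age_mean = 77.98, age_sd = 8.37, age_min = 65,
                       prop_female = 0.533,
                       ltc_fraction = 0.02,
                       comorbidity_prevalence = c(
                         diabetes = 0.387,
                         congestive_heart_failure = 0.156,
                         myocardial_infarction = 0.091,
                         copd = 0.334,
                         asthma = 0.107,
                         coronary_artery_disease = 0.160,
                         hypertension = 0.710,
                         cancer = 0.376,
                         chronic_kidney_disease = 0.163
                       ),
                       medication_prevalence = c(
                         interacting_drugs = 0.006,
                         immunosuppressive_meds = 0.249
                       ),
                       episodes_per_patient_lambda = 1.28,
                       visit_pmf = c(`1` = 0.60, `2` = 0.22, `3` = 0.09,
                                     `4` = 0.05, `5` = 0.03, `6` = 0.01),
                       prescribe_probability = 0.49,
                       category_mix = c(
                         guideline_adherent = 0.02,
                         clinically_appropriate = 0.61,
                         effective_but_unnecessary = 0.20,
                         undertreatment = 0.11,
                         not_recommended = 0.06
                       ),
                       duration_pmf = c(`7` = 0.54, `10` = 0.25, `5` = 0.21),
                       hospitalization_probability = 0.03,
                       chronic_rate = 0.01,
                       decoy_rate = 0.10,
                       edge_case_rate = 0) {
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    years = as.integer(years), epoch = as.Date(epoch), provinces = provinces,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    prop_female = prop_female, ltc_fraction = ltc_fraction,
    comorbidity_prevalence = comorbidity_prevalence,
    medication_prevalence = medication_prevalence,
    episodes_per_patient_lambda = episodes_per_patient_lambda,
    visit_pmf = visit_pmf, prescribe_probability = prescribe_probability,
    category_mix = category_mix, duration_pmf = duration_pmf,
    hospitalization_probability = hospitalization_probability,
    chronic_rate = chronic_rate, decoy_rate = decoy_rate,
    edge_case_rate = edge_case_rate
  )
  validate_sim_config(cfg)
  class(cfg) <- "cap_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(sprintf("invalid simulation config field '%s': %s", field, msg), call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) bad("n_patients", "must be >= 0")
  if (cfg$age_min < 65) bad("age_min", "cohort minimum age is 65")
  probs <- list(prop_female = cfg$prop_female, ltc_fraction = cfg$ltc_fraction,
                prescribe_probability = cfg$prescribe_probability,
                hospitalization_probability = cfg$hospitalization_probability,
                chronic_rate = cfg$chronic_rate, decoy_rate = cfg$decoy_rate,
                edge_case_rate = cfg$edge_case_rate)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) bad(nm, "must be a probability in [0, 1]")
  }
  for (nm in c("comorbidity_prevalence", "medication_prevalence", "provinces")) {
    v <- cfg[[nm]]
    if (is.null(names(v)) || any(v < 0) || any(v > 1)) bad(nm, "must be a named vector of probabilities")
  }
  if (abs(sum(cfg$category_mix) - 1) > 1e-9) bad("category_mix", "must sum to 1")
  if (!setequal(names(cfg$category_mix), quality_categories())) {
    bad("category_mix", paste("must name exactly:", paste(quality_categories(), collapse = ", ")))
  }
  dur_days <- as.integer(names(cfg$duration_pmf))
  if (anyNA(dur_days) || any(dur_days < 1) || any(dur_days > 30)) {
    bad("duration_pmf", "support must lie in [1, 30]")
  }
  if (abs(sum(cfg$duration_pmf) - 1) > 1e-9) bad("duration_pmf", "must sum to 1")
  if (abs(sum(cfg$visit_pmf) - 1) > 1e-9) bad("visit_pmf", "must sum to 1")
  if (abs(sum(cfg$provinces) - 1) > 1e-9) bad("provinces", "must sum to 1")
  invisible(cfg)
}

#' Generate the synthetic patient registry
#'
#' @param config a [sim_config()].
#' @return tibble: `patient_id`, `age` (truncated normal, minimum 65), `sex`
#'   (`"F"`/`"M"`), `province`, `long_term_care`, `income_quintile`, `rural`.
#'   Deterministic for a fixed seed; `n_patients = 0` yields an empty table
#'   with the full header.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_patients
  empty <- tibble::tibble(
    patient_id = character(0), age = integer(0), sex = character(0),
    province = character(0), long_term_care = logical(0),
    income_quintile = integer(0), rural = logical(0)
  )
  if (n == 0) return(empty)
  set.seed(derive_seed(config$seed, 1L))
  age <- round(rnorm(n, config$age_mean, config$age_sd))
  while (any(age < config$age_min)) {   # truncate by resampling below the floor
    i <- age < config$age_min
    age[i] <- round(rnorm(sum(i), config$age_mean, config$age_sd))
  }
  tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = as.integer(age),
    sex = ifelse(runif(n) < config$prop_female, "F", "M"),
    province = sample_int(names(config$provinces), n, replace = TRUE,
                          prob = config$provinces),
    long_term_care = runif(n) < config$ltc_fraction,
    income_quintile = sample_int(1:5, n, replace = TRUE),
    rural = runif(n) < 0.15
  )
}

# representative claim code emitted for each true condition (prefix-matches
# the shipped code configuration)
condition_claim_codes <- function() {
  c(diabetes = "2500", congestive_heart_failure = "4280",
    myocardial_infarction = "410", copd = "4919", asthma = "49390",
    coronary_artery_disease = "4140", hypertension = "4019",
    cancer = "1629", chronic_kidney_disease = "5859")
}

# regimen tables: every row reproduces an exact daily dose so the intended
# concordance direction is unambiguous under the default 10% tolerance
first_line_regimens <- function(kind = c("within", "below", "above")) {
  kind <- match.arg(kind)
  upd <- switch(kind,
    within = list(amox = c(4, 5, 6), clav = 2, doxy = 2),
    below = list(amox = 3, clav = 1, doxy = 1),
    above = list(amox = 7, clav = 3, doxy = 3)
  )
  tibble::tibble(
    agent = c(rep("amoxicillin", length(upd$amox)), "amoxicillin-clavulanate", "doxycycline"),
    atc_code = c(rep("J01CA04", length(upd$amox)), "J01CR02", "J01AA02"),
    strength_mg = c(rep(500, length(upd$amox)), 875, 100),
    units_per_day = c(upd$amox, upd$clav, upd$doxy),
    weight = c(rep(0.40 / length(upd$amox), length(upd$amox)), 0.17, 0.43)
  )
}

non_first_line_regimens <- function(category = c("clinically_appropriate", "not_recommended")) {
  category <- match.arg(category)
  if (category == "clinically_appropriate") {
    tibble::tribble(
      ~agent,           ~atc_code, ~strength_mg, ~units_per_day, ~weight,
      "levofloxacin",   "J01MA12", 500,          1,              0.30,
      "moxifloxacin",   "J01MA14", 400,          1,              0.18,
      "azithromycin",   "J01FA10", 250,          1,              0.25,
      "clarithromycin", "J01FA09", 500,          2,              0.15,
      "cefuroxime",     "J01DC02", 500,          2,              0.12
    )
  } else {
    tibble::tribble(
      ~agent,                          ~atc_code, ~strength_mg, ~units_per_day, ~weight,
      "azithromycin",                  "J01FA10", 250,          1,              0.30,
      "clarithromycin",                "J01FA09", 500,          2,              0.12,
      "levofloxacin",                  "J01MA12", 500,          1,              0.22,
      "moxifloxacin",                  "J01MA14", 400,          1,              0.13,
      "cefuroxime",                    "J01DC02", 500,          2,              0.11,
      "sulfamethoxazole-trimethoprim", "J01EE01", 800,          2,              0.12
    )
  }
}

sample_regimen <- function(tab, n) {
  if (n == 0) return(tab[0, , drop = FALSE])
  tab[sample.int(nrow(tab), n, replace = TRUE, prob = tab$weight), , drop = FALSE]
}

#' Generate synthetic claims tables with ground truth
#'
#' Emits the physician-visit, dispensation and hospital-admission tables for
#' a registry from [generate_cohort()], together with the ground-truth labels
#' the generator intended, so every downstream stage of the pipeline can be
#' verified exactly.  See [sim_config()] for the generative model and the
#' guarantees that make the noiseless round trip exact.
#'
#' @param config the [sim_config()] the registry was generated with.
#' @param registry output of [generate_cohort()].
#' @return a list of tibbles: `visits`, `dispensations`, `admissions`, and
#'   `truth` (list with `episodes` — per-episode intended labels — and
#'   `patients` — true comorbidity sets).
#' @export
generate_claims <- function(config, registry) {
  validate_sim_config(config)
  assert_columns(registry, c("patient_id", "province", "long_term_care"), "registry")
  if (anyDuplicated(registry$patient_id)) {
    stop("registry contains duplicated patient ids", call. = FALSE)
  }
  n <- nrow(registry)
  epoch <- config$epoch
  study_days <- days_between(epoch, as.Date(sprintf("%d-12-31", max(config$years)))) + 1L

  empty_visits <- tibble::tibble(patient_id = character(0), service_date = as.Date(character(0)),
                                 diagnostic_code = character(0), code_system = character(0),
                                 provider_type = character(0))
  empty_dsp <- tibble::tibble(record_id = integer(0), patient_id = character(0),
                              dispense_date = as.Date(character(0)), agent = character(0),
                              atc_code = character(0), strength_mg = numeric(0),
                              quantity = numeric(0), days_supply = numeric(0),
                              form = character(0))
  empty_adm <- tibble::tibble(patient_id = character(0), admission_date = as.Date(character(0)),
                              discharge_date = as.Date(character(0)), diagnosis_codes = character(0))
  if (n == 0) {
    return(list(visits = empty_visits, dispensations = empty_dsp, admissions = empty_adm,
                truth = list(episodes = tibble::tibble(), patients = tibble::tibble())))
  }

  conds <- names(config$comorbidity_prevalence)
  meds <- names(config$medication_prevalence)

  ## -- stream 2: patient-level comorbidity truth ---------------------------
  set.seed(derive_seed(config$seed, 2L))
  patients <- tibble::tibble(patient_id = registry$patient_id)
  for (cc in conds) patients[[cc]] <- runif(n) < config$comorbidity_prevalence[[cc]]
  for (mm in meds) patients[[mm]] <- runif(n) < config$medication_prevalence[[mm]]

  ## -- stream 3: episode skeleton (counts, placement, visits) --------------
  set.seed(derive_seed(config$seed, 3L))
  k <- pmin(1L + rpois(n, config$episodes_per_patient_lambda), 8L)
  block <- study_days %/% k                          # >= 228 days for k <= 8
  pat_idx <- rep(seq_len(n), k)
  ep_seq <- unlist(lapply(k, seq_len), use.names = FALSE)
  n_ep <- length(pat_idx)
  block_i <- block[pat_idx]
  # episode starts sit in disjoint blocks, >= 65 days apart by construction
  start_off <- (ep_seq - 1L) * block_i + floor(runif(n_ep) * (block_i - 65L))

  chronic <- runif(n_ep) < config$chronic_rate
  nv <- as.integer(sample_int(names(config$visit_pmf), n_ep, replace = TRUE,
                              prob = config$visit_pmf))
  gaps <- matrix(sample_int(1:6, n_ep * 5L, replace = TRUE), nrow = n_ep)  # span <= 30
  if (any(chronic)) {                       # deliberate chronic runs: 0,14,28,42
    nv[chronic] <- 4L
    gaps[chronic, 1:3] <- 14L
  }
  cum <- gaps
  for (j in 2:5) cum[, j] <- cum[, j - 1L] + gaps[, j]
  offsets <- cbind(0L, cum)                 # visit-day offsets from index
  span <- offsets[cbind(seq_len(n_ep), nv)]

  ep <- tibble::tibble(
    patient_id = registry$patient_id[pat_idx],
    province = registry$province[pat_idx],
    long_term_care = registry$long_term_care[pat_idx],
    episode_seq = ep_seq,
    index_date = epoch + start_off,
    span_days = as.integer(span),
    n_visits = nv,
    chronic = chronic
  )
  ep$end_date <- ep$index_date + ep$span_days

  # CAP visit rows (per-visit diagnosis codes in the provincial dialect)
  vis_ep <- rep(seq_len(n_ep), nv)
  vis_off <- offsets[cbind(vis_ep, unlist(lapply(nv, seq_len), use.names = FALSE))]
  is_bc <- ep$province[vis_ep] == names(config$provinces)[1]
  n_vis <- length(vis_ep)
  code <- character(n_vis)
  code[is_bc] <- sample_int(c("480", "481"), sum(is_bc), replace = TRUE, prob = c(0.2, 0.8))
  code[!is_bc] <- sample_int(c("486", "986"), sum(!is_bc), replace = TRUE, prob = c(0.9, 0.1))
  cap_visits <- tibble::tibble(
    patient_id = ep$patient_id[vis_ep],
    service_date = ep$index_date[vis_ep] + vis_off,
    diagnostic_code = code,
    code_system = ifelse(is_bc, "ICD9", "OHIP"),
    provider_type = "GP"
  )

  ## -- stream 4: comorbidity evidence rows ---------------------------------
  set.seed(derive_seed(config$seed, 4L))
  cond_codes <- condition_claim_codes()
  cond_truth <- as.matrix(patients[, conds])[pat_idx, , drop = FALSE]
  sel <- which(t(cond_truth))               # row-major: conditions grouped per episode
  ev_ep <- (sel - 1L) %/% length(conds) + 1L
  ev_cond <- conds[(sel - 1L) %% length(conds) + 1L]
  comorb_visits <- tibble::tibble(
    patient_id = ep$patient_id[ev_ep],
    service_date = ep$index_date[ev_ep] - sample_int(30:300, length(ev_ep), replace = TRUE),
    diagnostic_code = unname(cond_codes[ev_cond]),
    code_system = "ICD9",
    provider_type = "GP"
  )

  med_specs <- list(
    immunosuppressive_meds = list(agent = "mycophenolate", atc = "L04AA06", strength = 500),
    interacting_drugs = list(agent = "warfarin", atc = "B01AA03", strength = 5)
  )
  med_rows <- list()
  for (mm in meds) {
    has <- patients[[mm]][pat_idx]
    i <- which(has)
    if (length(i) == 0) next
    spec <- med_specs[[mm]]
    med_rows[[mm]] <- tibble::tibble(
      patient_id = ep$patient_id[i],
      dispense_date = ep$index_date[i] - sample_int(30:300, length(i), replace = TRUE),
      agent = spec$agent, atc_code = spec$atc,
      strength_mg = spec$strength, quantity = 30, days_supply = 30,
      form = "tablet"
    )
  }

  ## -- stream 5: admissions ------------------------------------------------
  set.seed(derive_seed(config$seed, 5L))
  hosp <- runif(n_ep) < config$hospitalization_probability
  hi <- which(hosp)
  admissions <- empty_adm
  if (length(hi) > 0) {
    adm_date <- ep$end_date[hi] + sample_int(0:5, length(hi), replace = TRUE)
    admissions <- tibble::tibble(
      patient_id = ep$patient_id[hi],
      admission_date = adm_date,
      discharge_date = adm_date + sample_int(3:10, length(hi), replace = TRUE),
      diagnosis_codes = "J18"
    )
  }
  ep$hospitalized <- hosp

  ## -- stream 6: prescribing -----------------------------------------------
  set.seed(derive_seed(config$seed, 6L))
  ep$prescribed <- runif(n_ep) < config$prescribe_probability
  med_any <- Reduce(`|`, lapply(meds, function(mm) patients[[mm]][pat_idx]),
                    init = logical(n_ep))
  cond_any <- rowSums(cond_truth) > 0
  has_just <- cond_any | med_any    # charlson >= 3 implies >= 2 conditions anyway
  ckd <- patients$chronic_kidney_disease[pat_idx]

  mix <- config$category_mix
  gen_category <- rep(NA_character_, n_ep)
  rx <- which(ep$prescribed)
  draw_group <- function(idx, feasible) {
    if (length(idx) == 0) return()
    w <- mix[feasible]
    # a mix concentrated on infeasible categories degenerates to uniform
    p <- if (sum(w) > 0) w / sum(w) else rep(1 / length(feasible), length(feasible))
    gen_category[idx] <<- sample_int(feasible, length(idx), replace = TRUE, prob = p)
  }
  draw_group(rx[!has_just[rx]],
             c("guideline_adherent", "effective_but_unnecessary",
               "undertreatment", "not_recommended"))
  draw_group(rx[has_just[rx]],
             c("guideline_adherent", "clinically_appropriate",
               "effective_but_unnecessary", "undertreatment"))

  agent <- rep(NA_character_, n_ep)
  atc <- rep(NA_character_, n_ep)
  strength <- rep(NA_real_, n_ep)
  upd <- rep(NA_real_, n_ep)
  duration <- rep(NA_real_, n_ep)

  assign_regimen <- function(idx, tab) {
    reg <- sample_regimen(tab, length(idx))
    agent[idx] <<- reg$agent
    atc[idx] <<- reg$atc_code
    strength[idx] <<- reg$strength_mg
    upd[idx] <<- reg$units_per_day
  }
  sample_duration <- function(nn, support = c("any", "above", "below")) {
    support <- match.arg(support)
    if (support == "any") {
      as.numeric(sample_int(names(config$duration_pmf), nn, replace = TRUE,
                            prob = config$duration_pmf))
    } else if (support == "above") {
      days <- as.numeric(names(config$duration_pmf))
      keep <- days > 5
      as.numeric(sample_int(names(config$duration_pmf)[keep], nn, replace = TRUE,
                            prob = config$duration_pmf[keep]))
    } else {
      rep(3, nn)
    }
  }

  i_ga <- which(gen_category == "guideline_adherent")
  assign_regimen(i_ga, first_line_regimens("within"))
  duration[i_ga] <- 5

  i_eb <- which(gen_category == "effective_but_unnecessary")
  if (length(i_eb) > 0) {
    dose_excess <- runif(length(i_eb)) < 0.08   # excess duration dominates
    assign_regimen(i_eb[dose_excess], first_line_regimens("above"))
    assign_regimen(i_eb[!dose_excess], first_line_regimens("within"))
    duration[i_eb] <- sample_duration(length(i_eb), "above")
  }

  i_ut <- which(gen_category == "undertreatment")
  if (length(i_ut) > 0) {
    scen <- sample_int(c("dose_below_dur_above", "dur_below", "dose_below", "both_below"),
                       length(i_ut), replace = TRUE, prob = c(0.80, 0.09, 0.06, 0.05))
    i1 <- i_ut[scen == "dose_below_dur_above"]
    assign_regimen(i1, first_line_regimens("below"))
    duration[i1] <- sample_duration(length(i1), "above")
    i2 <- i_ut[scen == "dur_below"]
    assign_regimen(i2, first_line_regimens("within"))
    duration[i2] <- 3
    i3 <- i_ut[scen == "dose_below"]
    assign_regimen(i3, first_line_regimens("below"))
    duration[i3] <- 5
    i4 <- i_ut[scen == "both_below"]
    assign_regimen(i4, first_line_regimens("below"))
    duration[i4] <- 3
  }

  i_ca <- which(gen_category == "clinically_appropriate")
  assign_regimen(i_ca, non_first_line_regimens("clinically_appropriate"))
  duration[i_ca] <- sample_duration(length(i_ca), "any")

  i_nr <- which(gen_category == "not_recommended")
  assign_regimen(i_nr, non_first_line_regimens("not_recommended"))
  duration[i_nr] <- sample_duration(length(i_nr), "any")

  # deliberately unclassifiable prescriptions (edge cases): agent outside the
  # shipped rule set, no intended label
  edge <- logical(n_ep)
  if (config$edge_case_rate > 0 && length(rx) > 0) {
    edge[rx] <- runif(length(rx)) < config$edge_case_rate
    ie <- which(edge)
    agent[ie] <- "nitrofurantoin"
    atc[ie] <- "J01XE01"
    strength[ie] <- 100
    upd[ie] <- 2
    duration[ie] <- 5
    gen_category[ie] <- NA_character_
  }

  rx_offset <- rep(NA_integer_, n_ep)
  rx_offset[rx] <- sample_int(0:2, length(rx), replace = TRUE)
  ep$record_id <- rep(NA_integer_, n_ep)
  ep$record_id[rx] <- seq_along(rx)

  rx_rows <- tibble::tibble(
    record_id = ep$record_id[rx],
    patient_id = ep$patient_id[rx],
    dispense_date = ep$index_date[rx] + rx_offset[rx],
    agent = agent[rx], atc_code = atc[rx],
    strength_mg = strength[rx],
    quantity = upd[rx] * duration[rx],
    days_supply = duration[rx],
    form = "tablet"
  )

  ## -- stream 7: decoy dispensations ---------------------------------------
  set.seed(derive_seed(config$seed, 7L))
  decoy_rows <- empty_dsp
  if (config$decoy_rate > 0 && length(rx) > 0) {
    di <- rx[runif(length(rx)) < config$decoy_rate]
    if (length(di) > 0) {
      type <- sample_int(c("in_window", "pre_window", "post_window"),
                         length(di), replace = TRUE, prob = c(0.5, 0.25, 0.25))
      off <- integer(length(di))
      lo <- rx_offset[di] + 1L                  # strictly after the intended record
      hi2 <- ep$span_days[di] + 5L              # still inside the linkage window
      iw <- type == "in_window"
      off[iw] <- lo[iw] + floor(runif(sum(iw)) * (hi2 - lo + 1L)[iw])
      ipre <- type == "pre_window"
      off[ipre] <- -sample_int(1:10, sum(ipre), replace = TRUE)
      ipost <- type == "post_window"
      off[ipost] <- hi2[ipost] + sample_int(1:10, sum(ipost), replace = TRUE)
      reg <- sample_regimen(non_first_line_regimens("not_recommended"), length(di))
      decoy_rows <- tibble::tibble(
        record_id = length(rx) + seq_along(di),
        patient_id = ep$patient_id[di],
        dispense_date = ep$index_date[di] + off,
        agent = reg$agent, atc_code = reg$atc_code,
        strength_mg = reg$strength_mg,
        quantity = reg$units_per_day * 7,
        days_supply = 7,
        form = "tablet"
      )
    }
  }

  med_tab <- dplyr::bind_rows(med_rows)
  if (nrow(med_tab) > 0) {
    med_tab$record_id <- length(rx) + nrow(decoy_rows) + seq_len(nrow(med_tab))
  }
  dispensations <- dplyr::bind_rows(rx_rows, decoy_rows, med_tab)
  dispensations <- dispensations[, names(empty_dsp)]

  intended <- gen_category
  reclass <- !is.na(intended) & intended == "undertreatment" & ckd
  intended[reclass] <- "clinically_appropriate"

  truth_eps <- tibble::tibble(
    patient_id = ep$patient_id,
    episode_seq = ep$episode_seq,
    index_date = ep$index_date,
    end_date = ep$end_date,
    span_days = ep$span_days,
    n_visits = ep$n_visits,
    long_term_care = ep$long_term_care,
    chronic = ep$chronic,
    hospitalized = ep$hospitalized,
    prescribed = ep$prescribed,
    record_id = ep$record_id,
    edge_case = edge,
    intended_category = intended,
    reclassified_from_undertreatment = reclass,
    has_any_justification = has_just,
    ckd = ckd
  )

  visits <- dplyr::bind_rows(cap_visits, comorb_visits)
  visits <- dplyr::arrange(visits, .data$patient_id, .data$service_date, .data$diagnostic_code)

  list(visits = visits, dispensations = dispensations, admissions = admissions,
       truth = list(episodes = truth_eps, patients = patients))
}

#' Generate and write the synthetic claims tables
#'
#' Runs [generate_cohort()] and [generate_claims()] and writes
#' `registry.csv`, `visits.csv`, `dispensations.csv`, `admissions.csv`,
#' `truth.csv` (episode-level ground truth joined with the patient-level
#' comorbidity truth) and a `data_dictionary.md` documenting every column.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return the [generate_claims()] list, invisibly, with `registry` added.
#' @export
simulate_claims <- function(config = sim_config(), out_dir) {
  registry <- generate_cohort(config)
  claims <- generate_claims(config, registry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(registry, file.path(out_dir, "registry.csv"))
  readr::write_csv(claims$visits, file.path(out_dir, "visits.csv"))
  readr::write_csv(claims$dispensations, file.path(out_dir, "dispensations.csv"))
  readr::write_csv(claims$admissions, file.path(out_dir, "admissions.csv"))
  truth_flat <- claims$truth$episodes
  if (nrow(truth_flat) > 0) {
    truth_flat <- dplyr::left_join(truth_flat, claims$truth$patients, by = "patient_id")
  }
  readr::write_csv(truth_flat, file.path(out_dir, "truth.csv"))
  writeLines(data_dictionary_text(), file.path(out_dir, "data_dictionary.md"))
  invisible(c(list(registry = registry), claims))
}

data_dictionary_text <- function() {
  c(
    "# Synthetic claims data dictionary",
    "",
    "## registry.csv",
    "- patient_id: opaque id (P######)",
    "- age: years at cohort entry (integer, >= 65)",
    "- sex: F/M",
    "- province: province label",
    "- long_term_care: TRUE for long-term-care residents (analysis exclusion)",
    "- income_quintile: 1-5",
    "- rural: TRUE for rural residence",
    "",
    "## visits.csv",
    "- patient_id",
    "- service_date: ISO-8601 date",
    "- diagnostic_code: billing diagnosis code (CAP or comorbidity)",
    "- code_system: ICD9 or OHIP tag for the code",
    "- provider_type: always GP here",
    "",
    "## dispensations.csv",
    "- record_id: integer id; linkage ties break on the smallest id",
    "- patient_id",
    "- dispense_date: ISO-8601 date",
    "- agent: canonical drug name",
    "- atc_code: 7-character ATC (J01* = systemic antibacterials)",
    "- strength_mg: mg of active component per unit (amoxicillin component",
    "  for combination products)",
    "- quantity: units dispensed",
    "- days_supply: intended duration in days",
    "- form: dose form",
    "",
    "## admissions.csv",
    "- patient_id",
    "- admission_date / discharge_date: ISO-8601 dates",
    "- diagnosis_codes: ;-separated ICD-10 codes",
    "",
    "## truth.csv (ground truth; the pipeline must never read this)",
    "- one row per intended episode with: episode_seq, index/end dates, span,",
    "  visit count, long_term_care / chronic / hospitalized exclusion flags,",
    "  prescribed flag, record_id of the intended first dispensation,",
    "  edge_case flag, intended_category, reclassified_from_undertreatment,",
    "  has_any_justification, ckd, and the patient-level true comorbidity",
    "  and medication-class flags"
  )
}
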