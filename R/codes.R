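#' Default diagnosis and medication code configuration
#'
#' Returns the shipped code lists used to (i) identify community-acquired
#' pneumonia (CAP) physician visits and (ii) flag patient clinical
#' justifications (comorbidities and medication classes) from coded claims.
#'
#' Pneumonia visit codes follow the provincial billing conventions: ICD-9
#' range `480-481` plus OHIP fee codes `486` and `986`.  ICD-9 entries may be
#' single codes (matched exactly after whitespace stripping) or ranges
#' `"480-481"`, which expand to every code sharing one of the 3-digit stems.
#' Condition code lists are matched by prefix (claims codes frequently carry
#' 4th/5th digits), with the same range expansion for ICD-9.  Medication
#' classes are matched by ATC prefix against dispensation records.
#'
#' All of this is configuration, not hard-wired logic: alternative provincial
#' dialects are supplied via [read_code_config()].
#'
#' @return a list with elements `cap_codes` (per code system), `conditions`
#'   (per condition, code lists per system) and `medication_classes` (ATC
#'   prefixes per class).
#' @export
#' @examples
#' cfg <- default_code_config()
#' names(cfg$conditions)
default_code_config <- function() {
  list(
    cap_codes = list(
      ICD9 = c("480-481"),
      OHIP = c("486", "986")
    ),
    conditions = list(
      diabetes                 = list(ICD9 = "250",            ICD10 = c("E10", "E11", "E13", "E14")),
      congestive_heart_failure = list(ICD9 = "428",            ICD10 = "I50"),
      myocardial_infarction    = list(ICD9 = c("410", "412"),  ICD10 = c("I21", "I22")),
      copd                     = list(ICD9 = c("491", "492", "496"), ICD10 = c("J43", "J44")),
      asthma                   = list(ICD9 = "493",            ICD10 = "J45"),
      coronary_artery_disease  = list(ICD9 = "414",            ICD10 = "I25"),
      hypertension             = list(ICD9 = c("401", "402"),  ICD10 = c("I10", "I11")),
      cancer                   = list(ICD9 = "140-208",        ICD10 = "C"),
      chronic_kidney_disease   = list(ICD9 = "585",            ICD10 = "N18")
    ),
    medication_classes = list(
      immunosuppressive_meds = list(ATC = c("L04A", "H02AB", "L01")),
      interacting_drugs      = list(ATC = c("B01AA"))
    )
  )
}

#' Read a code configuration from YAML
#'
#' @param path path to a YAML file with the structure of
#'   [default_code_config()].
#' @return validated code configuration list.
#' @export
read_code_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("code configuration file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validate_code_config(cfg)
}

validate_code_config <- function(cfg) {
  for (field in c("cap_codes", "conditions", "medication_classes")) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("code configuration is missing field '%s'", field), call. = FALSE)
    }
  }
  if (length(cfg$cap_codes) == 0) {
    stop("code configuration field 'cap_codes' is empty", call. = FALSE)
  }
  cfg$cap_codes <- lapply(cfg$cap_codes, as.character)
  cfg$conditions <- lapply(cfg$conditions, function(x) lapply(x, as.character))
  cfg$medication_classes <- lapply(cfg$medication_classes, function(x) lapply(x, as.character))
  cfg
}

# Expand a vector of ICD-9 entries into exact codes and 3-digit range stems.
# "480-481" -> stems "480" "481"; plain entries stay exact matches.
expand_icd9_entries <- function(entries) {
  entries <- trimws(as.character(entries))
  is_range <- grepl("^[0-9]{3}\\s*-\\s*[0-9]{3}$", entries)
  stems <- character(0)
  for (e in entries[is_range]) {
    ends <- as.integer(strsplit(e, "-")[[1]])
    stems <- c(stems, sprintf("%03d", seq(ends[1], ends[2])))
  }
  list(exact = entries[!is_range], stems = stems)
}

#' Filter physician visit claims to CAP diagnoses
#'
#' Keeps only visit rows whose diagnostic code belongs to the configured CAP
#' code set for the row's tagged code system.  Matching is exact string
#' comparison after whitespace stripping; ICD-9 range entries such as
#' `"480-481"` match every code whose 3-digit stem falls in the range.
#'
#' @param visits data frame with columns `patient_id`, `service_date`,
#'   `diagnostic_code`, `code_system`.
#' @param code_config code configuration, see [default_code_config()].
#' @return the CAP subset of `visits`, same columns.
#' @export
#' @examples
#' v <- tibble::tibble(patient_id = "p1", service_date = as.Date("2014-03-01"),
#'                     diagnostic_code = c("481", "250"),
#'                     code_system = "ICD9")
#' identify_cap_visits(v, default_code_config())
identify_cap_visits <- function(visits, code_config = default_code_config()) {
  assert_columns(visits, c("patient_id", "service_date", "diagnostic_code", "code_system"),
                 "visits")
  code_config <- validate_code_config(code_config)
  systems <- unique(as.character(visits$code_system))
  unknown <- setdiff(systems, names(code_config$cap_codes))
  if (length(unknown) > 0) {
    stop(sprintf("unknown code-system tag(s) in visits: %s (configured: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(code_config$cap_codes), collapse = ", ")),
         call. = FALSE)
  }
  code <- trimws(as.character(visits$diagnostic_code))
  keep <- logical(nrow(visits))
  for (sys in systems) {
    idx <- visits$code_system == sys
    entries <- code_config$cap_codes[[sys]]
    if (identical(sys, "ICD9")) {
      ex <- expand_icd9_entries(entries)
      keep[idx] <- code[idx] %in% ex$exact | substr(code[idx], 1, 3) %in% ex$stems
    } else {
      keep[idx] <- code[idx] %in% trimws(entries)
    }
  }
  visits[keep, , drop = FALSE]
}

# prefixes for one condition+system, with ICD-9 ranges expanded to stems
condition_prefixes <- function(cond_cfg, system) {
  entries <- cond_cfg[[system]]
  if (is.null(entries)) return(character(0))
  if (identical(system, "ICD9")) {
    ex <- expand_icd9_entries(entries)
    c(ex$exact, ex$stems)
  } else {
    trimws(as.character(entries))
  }
}

# TRUE where any prefix matches the start of code
matches_any_prefix <- function(codes, prefixes) {
  if (length(prefixes) == 0 || length(codes) == 0) return(logical(length(codes)))
  out <- logical(length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
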