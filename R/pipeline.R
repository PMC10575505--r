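#' Assemble a pipeline configuration
#'
#' Collects every analysis parameter, the input locations (either CSV paths
#' or in-memory tables), and the output directory into one validated list.
#' Parameters default to the published analysis settings: 14-day episode
#' gap, 30-day chronic-span limit, 5-day hospitalisation and linkage
#' follow-up, 365-day comorbidity lookback, minimum reportable cell of 6,
#' Charlson moderate/severe threshold of 3 and a 10% dose tolerance.
#'
#' @param path optional YAML file; its entries are defaults that the `...`
#'   overrides replace.
#' @param ... named overrides: `inputs` (named list of paths for `visits`,
#'   `dispensations`, `admissions`, optional `registry`), `data` (named list
#'   of in-memory tables, same names), `simulate` (a [sim_config()] to
#'   generate inputs instead), `out_dir`, `code_config`, `rules`,
#'   `gap_days`, `max_span_days`, `followup_days`, `linkage_followup_days`,
#'   `lookback_days`, `min_cell`, `charlson_threshold`, `dose_tolerance`,
#'   `duration_tolerance`, `reference_year`, `annual_population`, `seed`.
#' @return a `cap_pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    inputs = NULL, data = NULL, simulate = NULL, out_dir = NULL,
    code_config = default_code_config(), rules = default_rules(),
    gap_days = 14, max_span_days = 30, followup_days = 5,
    linkage_followup_days = 5, lookback_days = 365, min_cell = 6,
    charlson_threshold = 3, dose_tolerance = 0.10, duration_tolerance = 0,
    reference_year = NULL, annual_population = NULL, seed = 1L
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("pipeline config file not found: %s", path), call. = FALSE)
    y <- yaml::read_yaml(path)
    if (!is.null(y$code_config)) y$code_config <- read_code_config(y$code_config)
    if (!is.null(y$rules)) y$rules <- read_rules(y$rules)
    if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (fld in c("gap_days", "max_span_days", "followup_days", "linkage_followup_days",
                "lookback_days", "min_cell", "charlson_threshold")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) < 1 || any(v < 0)) {
      stop(sprintf("invalid pipeline config field '%s'", fld), call. = FALSE)
    }
  }
  class(cfg) <- "cap_pipeline_config"
  cfg
}

resolve_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- generate_cohort(config$simulate)
    claims <- generate_claims(config$simulate, sim)
    return(list(registry = sim, visits = claims$visits,
                dispensations = claims$dispensations, admissions = claims$admissions,
                truth = claims$truth, paths = NULL))
  }
  if (!is.null(config$data)) {
    d <- config$data
    for (fld in c("visits", "dispensations", "admissions")) {
      if (is.null(d[[fld]])) stop(sprintf("pipeline config 'data' is missing '%s'", fld), call. = FALSE)
    }
    return(list(registry = d$registry, visits = d$visits,
                dispensations = d$dispensations, admissions = d$admissions,
                truth = NULL, paths = NULL))
  }
  if (is.null(config$inputs)) {
    stop("pipeline config needs one of 'inputs', 'data' or 'simulate'", call. = FALSE)
  }
  paths <- config$inputs
  for (fld in c("visits", "dispensations", "admissions")) {
    if (is.null(paths[[fld]])) {
      stop(sprintf("pipeline config 'inputs' is missing the '%s' path", fld), call. = FALSE)
    }
  }
  for (fld in c("visits", "dispensations", "admissions")) {
    if (!file.exists(paths[[fld]])) {
      stop(sprintf("input file for '%s' not found: %s", fld, paths[[fld]]), call. = FALSE)
    }
  }
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  registry <- NULL
  if (!is.null(paths$registry)) {
    if (!file.exists(paths$registry)) {
      stop(sprintf("input file for 'registry' not found: %s", paths$registry), call. = FALSE)
    }
    registry <- rd(paths$registry)
  }
  list(registry = registry, visits = rd(paths$visits),
       dispensations = rd(paths$dispensations), admissions = rd(paths$admissions),
       truth = NULL, paths = paths)
}

#' Run the full prescribing-quality pipeline
#'
#' Executes, in order: cohort filtering (age >= 65, long-term-care residents
#' removed when a registry is supplied), CAP visit identification, episode
#' construction, chronic-span and hospitalisation exclusions, first-
#' dispensation linkage, justification profiling, quality classification,
#' annual rates, Poisson trends, and the duration / ATC-class summaries.
#' Episode exclusions are flags, never deletions, and the stage row counts
#' are asserted to add up (`episodes = kept + chronic + hospitalized`).
#'
#' @param config a [pipeline_config()].
#' @return a list with the stage outputs (`episodes`, `linked`, `justifications`,
#'   `classified`, `rates`, `trends`, `duration_freq`, `atc_breakdown`) and a
#'   `manifest` (parameters, per-stage row counts, input hashes, warnings)
#'   that makes reruns reproducible.  When `config$out_dir` is set the
#'   tables and the manifest are also written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  inputs <- resolve_inputs(config)
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  visits <- inputs$visits
  registry <- inputs$registry
  if (!is.null(registry)) {
    assert_columns(registry, c("patient_id"), "registry")
    keep <- rep(TRUE, nrow(registry))
    if ("age" %in% names(registry)) keep <- keep & registry$age >= 65
    if ("long_term_care" %in% names(registry)) keep <- keep & !registry$long_term_care
    excluded_patients <- registry$patient_id[!keep]
    if (length(excluded_patients) > 0) {
      note(sprintf("excluded %d registry patients (age < 65 or long-term care)",
                   length(excluded_patients)))
    }
    cohort_ids <- as.character(registry$patient_id[keep])
    visits <- visits[as.character(visits$patient_id) %in% cohort_ids, , drop = FALSE]
  }

  cap <- identify_cap_visits(visits, config$code_config)
  episodes <- build_episodes(cap, gap_days = config$gap_days,
                             max_span_days = config$max_span_days)
  episodes <- exclude_hospitalized(episodes, inputs$admissions,
                                   followup_days = config$followup_days)
  n_chronic <- sum(episodes$exclusion_reason == "chronic_span")
  n_hosp <- sum(episodes$exclusion_reason == "hospitalized")
  n_kept <- sum(!episodes$excluded)
  stopifnot(nrow(episodes) == n_kept + n_chronic + n_hosp)

  linked <- withCallingHandlers(
    link_prescriptions(episodes, inputs$dispensations,
                       followup_days = config$linkage_followup_days),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  rx <- linked[linked$prescribed, , drop = FALSE]
  just <- build_justification_table(
    rx, visits = visits, admissions = inputs$admissions,
    dispensations = inputs$dispensations, code_config = config$code_config,
    lookback_days = config$lookback_days,
    charlson_threshold = config$charlson_threshold
  )
  concord <- assess_concordance(rx, config$rules,
                                dose_tolerance = config$dose_tolerance,
                                duration_tolerance = config$duration_tolerance)
  classified <- classify_prescriptions(rx, just, concordance = concord,
                                       rules = config$rules)
  classified$year <- as.integer(format(classified$index_date, "%Y"))

  # annual denominators: configured table, else the filtered cohort size
  years <- sort(unique(classified$year))
  pop <- config$annual_population
  if (is.null(pop)) {
    n_cohort <- if (!is.null(registry)) length(unique(visits$patient_id)) else
      length(unique(episodes$patient_id))
    pop <- setNames(rep(n_cohort, length(years)), years)
  }
  counts <- dplyr::count(classified, .data$category, .data$year, name = "count",
                         .drop = FALSE)
  counts$population <- as.numeric(pop[as.character(counts$year)])
  counts <- counts[!is.na(counts$population), , drop = FALSE]
  counts$rate_per_1000 <- rate_per_1000(counts$count, counts$population)

  trends <- dplyr::bind_rows(lapply(split(counts, counts$category), function(d) {
    if (nrow(d) < 2) return(NULL)
    res <- poisson_trend(d[, c("year", "count", "population")],
                         reference_year = config$reference_year %||% min(d$year))
    res$category <- d$category[1]
    res
  }))

  duration_freq <- duration_frequency(classified, config$rules, first_line_only = TRUE,
                                      min_n = config$min_cell)
  atc_breakdown <- atc_class_breakdown(classified, min_n = config$min_cell)

  manifest <- list(
    parameters = list(
      gap_days = config$gap_days, max_span_days = config$max_span_days,
      followup_days = config$followup_days,
      linkage_followup_days = config$linkage_followup_days,
      lookback_days = config$lookback_days, min_cell = config$min_cell,
      charlson_threshold = config$charlson_threshold,
      dose_tolerance = config$dose_tolerance,
      duration_tolerance = config$duration_tolerance,
      seed = config$seed
    ),
    input_hashes = if (!is.null(inputs$paths))
      as.list(tools::md5sum(unlist(inputs$paths))) else NULL,
    row_counts = list(
      visits_in = nrow(inputs$visits), cap_visits = nrow(cap),
      episodes = nrow(episodes), episodes_kept = n_kept,
      episodes_excluded_chronic = n_chronic,
      episodes_excluded_hospitalized = n_hosp,
      linked = nrow(linked), prescribed = nrow(rx),
      classified = nrow(classified)
    ),
    warnings = warnings_log
  )

  out <- list(episodes = episodes, linked = linked, justifications = just,
              classified = classified, annual_counts = counts, trends = trends,
              duration_freq = duration_freq, atc_breakdown = atc_breakdown,
              truth = inputs$truth, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
      readr::write_csv(df, file.path(config$out_dir, name))
    }
    wr(episodes, "episodes.csv")
    wr(linked, "linked.csv")
    wr(classified, "classified.csv")
    wr(counts, "rates.csv")
    if (!is.null(trends) && nrow(trends) > 0) wr(trends, "trends.csv")
    wr(duration_freq, "duration_freq.csv")
    wr(atc_breakdown, "atc_breakdown.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Render summary report tables
#'
#' Produces a cohort-characteristics table and a category-by-year table
#' (counts, crude rates per 1000, percentage difference and Poisson rate
#' ratio with 95% CI) from a [run_pipeline()] result, with small-cell
#' suppression applied, as data frames and as markdown text.
#'
#' @param result a [run_pipeline()] return value.
#' @param min_cell suppression threshold; default 6.
#' @return list with `category_table` (tibble) and `markdown` (character
#'   vector of lines).
#' @export
render_report <- function(result, min_cell = 6) {
  counts <- result$annual_counts
  wide <- tidyr::pivot_wider(
    counts[, c("category", "year", "count", "rate_per_1000")],
    names_from = "year", values_from = c("count", "rate_per_1000")
  )
  yrs <- sort(unique(counts$year))
  first <- counts[counts$year == min(yrs), c("category", "rate_per_1000")]
  last <- counts[counts$year == max(yrs), c("category", "rate_per_1000")]
  delta <- dplyr::left_join(first, last, by = "category", suffix = c("_start", "_end"))
  delta$delta <- pct_difference(delta$rate_per_1000_start, delta$rate_per_1000_end)
  tab <- dplyr::left_join(wide, delta[, c("category", "delta")], by = "category")
  if (!is.null(result$trends) && nrow(result$trends) > 0) {
    tr <- result$trends
    tr$rate_ratio_ci <- sprintf("%.2f (%.2f-%.2f)", tr$rate_ratio, tr$ci_low, tr$ci_high)
    tab <- dplyr::left_join(tab, tr[, c("category", "rate_ratio_ci")], by = "category")
  }
  for (cl in grep("^count_", names(tab), value = TRUE)) {
    tab[[cl]] <- suppress_small_cells(tab[[cl]], min_n = min_cell)
  }
  md <- c(
    "# Prescribing quality by category and year",
    "",
    paste0("| ", paste(names(tab), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
    apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
  list(category_table = tab, markdown = md)
}
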