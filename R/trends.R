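#' Prescribing rate per 1000 population
#'
#' Crude when a single count/population pair (or parallel vectors) is given;
#' directly age-standardised when band-level counts, populations and
#' reference weights are supplied: `1000 * sum(w_b * count_b /
#' population_b)` with the weights summing to 1.
#'
#' @param count event count(s).
#' @param population denominator(s); must be positive wherever the count is
#'   nonzero.
#' @param weights optional reference weights, one per band, summing to 1.
#' @return rate per 1000 (vectorised in the crude case, scalar when
#'   standardised).
#' @export
#' @examples
#' rate_per_1000(100, 10000)                      # 10
#' rate_per_1000(c(10, 20), c(1000, 1000), c(0.6, 0.4))  # 14
rate_per_1000 <- function(count, population, weights = NULL) {
  if (any(population <= 0 & count > 0)) {
    stop("zero population band with nonzero count", call. = FALSE)
  }
  if (is.null(weights)) {
    return(1000 * count / population)
  }
  if (length(weights) != length(count) || length(count) != length(population)) {
    stop("count, population and weights must have one entry per age band", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("standardisation weights must sum to 1", call. = FALSE)
  }
  1000 * sum(weights * count / population)
}

#' Percentage difference between two rates
#'
#' `(rate_end - rate_start) / rate_start`, reported to two decimals, as used
#' to summarise the change between the first and last study year.
#'
#' @param rate_start baseline rate (> 0).
#' @param rate_end final rate.
#' @return the relative change rounded to 2 decimals; `NA` when the baseline
#'   is zero.
#' @export
#' @examples
#' pct_difference(2.16, 6.93)  # 2.21
pct_difference <- function(rate_start, rate_end) {
  out <- ifelse(rate_start == 0, NA_real_,
                round((rate_end - rate_start) / rate_start, 2))
  out
}

#' Poisson rate-ratio trend over calendar years
#'
#' Fits the log-linear count model `log E[count_y] = alpha + beta_y +
#' log(population_y)` with year as a categorical predictor (first year as
#' reference unless stated) and the annual cohort population as offset,
#' by iteratively reweighted least squares (relative tolerance 1e-8).
#' Returns the rate ratio `exp(beta)` for the comparison year with a 95%
#' Wald interval on the log scale and a two-sided p-value.
#'
#' A zero count in the reference year makes the reference log-rate diverge;
#' in that case 0.5 is added to every count (continuity correction) and the
#' result is flagged `continuity_corrected`.
#'
#' @param counts data frame with columns `year`, `count`, `population`
#'   (one row per year; at least two years, all populations positive).
#' @param reference_year,comparison_year years compared; default first and
#'   last year present.
#' @param linear_year fit year as a linear term instead; the rate ratio then
#'   reports the per-year multiplicative trend and the comparison/reference
#'   years are informational.
#' @return one-row tibble: `rate_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `reference_year`, `comparison_year`, `continuity_corrected`.
#' @export
poisson_trend <- function(counts, reference_year = NULL, comparison_year = NULL,
                          linear_year = FALSE) {
  assert_columns(counts, c("year", "count", "population"), "annual counts")
  counts <- dplyr::arrange(tibble::as_tibble(counts), .data$year)
  if (nrow(counts) < 2) stop("poisson_trend needs at least two years of data", call. = FALSE)
  if (any(counts$population <= 0)) stop("all populations must be positive", call. = FALSE)
  reference_year <- reference_year %||% min(counts$year)
  comparison_year <- comparison_year %||% max(counts$year)
  if (!reference_year %in% counts$year || !comparison_year %in% counts$year) {
    stop("reference and comparison years must be present in the data", call. = FALSE)
  }

  continuity <- FALSE
  ref_count <- counts$count[counts$year == reference_year]
  if (any(ref_count == 0)) {
    counts$count <- counts$count + 0.5
    continuity <- TRUE
  }

  counts$year_f <- stats::relevel(factor(counts$year), ref = as.character(reference_year))
  # the continuity correction makes counts non-integer; that warning is expected
  quiet_glm <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  }
  fit <- if (linear_year) {
    quiet_glm(glm(count ~ I(year - reference_year) + offset(log(population)),
                  family = poisson(), data = counts,
                  control = list(epsilon = 1e-8, maxit = 100)))
  } else {
    quiet_glm(glm(count ~ year_f + offset(log(population)),
                  family = poisson(), data = counts,
                  control = list(epsilon = 1e-8, maxit = 100)))
  }
  sm <- summary(fit)$coefficients
  term <- if (linear_year) rownames(sm)[2] else paste0("year_f", comparison_year)
  if (!term %in% rownames(sm)) stop("comparison-year coefficient not found", call. = FALSE)
  beta <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  tibble::tibble(
    rate_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    reference_year = reference_year,
    comparison_year = comparison_year,
    continuity_corrected = continuity
  )
}

#' Frequency of therapy durations
#'
#' Tabulates dispensed durations (days supply) of linked prescriptions,
#' optionally restricted to first-line agents, by optional strata, with
#' small-cell suppression applied to the reported table.
#'
#' @param linked prescribed rows of [link_prescriptions()] output (or any
#'   frame with `agent`, `atc_code`, `duration_days`).
#' @param rules rule set used to identify first-line agents.
#' @param first_line_only restrict to first-line agents; default TRUE.
#' @param by character vector of stratum columns present in `linked`.
#' @param suppress apply [suppress_small_cells()] to the output; default
#'   TRUE.
#' @param min_n suppression threshold; default 6.
#' @return tibble of `duration_days`, stratum columns, `n` and `proportion`
#'   (within stratum).
#' @export
duration_frequency <- function(linked, rules = default_rules(),
                               first_line_only = TRUE, by = character(0),
                               suppress = TRUE, min_n = 6) {
  rx <- linked[!is.na(linked$duration_days), , drop = FALSE]
  if (first_line_only) {
    conc <- assess_concordance(rx, rules)
    rx <- rx[conc$agent_concordant, , drop = FALSE]
  }
  grp <- c(by, "duration_days")
  tab <- dplyr::count(rx, dplyr::across(dplyr::all_of(grp)), name = "n")
  tab <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(by)))
  tab <- dplyr::mutate(tab, proportion = .data$n / sum(.data$n))
  tab <- dplyr::ungroup(tab)
  tab <- dplyr::arrange(tab, dplyr::across(dplyr::all_of(by)), .data$duration_days)
  if (suppress) tab <- suppress_small_cells(tab, "n", "proportion", min_n = min_n)
  tab
}

#' Major ATC class of an antibiotic code
#'
#' Maps 7-character (or prefix) ATC codes to the reporting classes used for
#' the non-first-line breakdowns: macrolides (J01FA), fluoroquinolones
#' (J01MA), tetracyclines (J01AA), other beta-lactams (J01C/J01D) and
#' `other` for anything else (including unmappable codes).
#'
#' @param atc_code character vector of ATC codes.
#' @return character vector of class labels.
#' @export
atc_major_class <- function(atc_code) {
  code <- as.character(atc_code)
  out <- rep("other", length(code))
  out[startsWith(code, "J01C") | startsWith(code, "J01D")] <- "other_beta_lactams"
  out[startsWith(code, "J01AA")] <- "tetracyclines"
  out[startsWith(code, "J01MA")] <- "fluoroquinolones"
  out[startsWith(code, "J01FA")] <- "macrolides"
  out
}

#' ATC-class breakdown of selected quality categories
#'
#' Relative proportions of prescriptions per major ATC class, by quality
#' category (and optional strata).  Used for the post-hoc summaries of the
#' clinically-appropriate and not-recommended categories.
#'
#' @param classified output of [classify_prescriptions()].
#' @param categories categories to summarise; default clinically appropriate
#'   and not recommended.
#' @param by extra stratum columns.
#' @param suppress,min_n small-cell suppression of the reported table.
#' @return tibble of `category`, stratum columns, `atc_class`, `n`,
#'   `proportion` (summing to 1 within category x stratum before
#'   suppression).
#' @export
atc_class_breakdown <- function(classified,
                                categories = c("clinically_appropriate", "not_recommended"),
                                by = character(0), suppress = TRUE, min_n = 6) {
  assert_columns(classified, c("category", "atc_code"), "classified prescriptions")
  rx <- classified[as.character(classified$category) %in% categories, , drop = FALSE]
  rx$atc_class <- atc_major_class(rx$atc_code)
  grp <- c("category", by, "atc_class")
  tab <- dplyr::count(rx, dplyr::across(dplyr::all_of(grp)), name = "n")
  tab <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(c("category", by))))
  tab <- dplyr::mutate(tab, proportion = .data$n / sum(.data$n))
  tab <- dplyr::ungroup(tab)
  if (suppress) tab <- suppress_small_cells(tab, "n", "proportion", min_n = min_n)
  tab
}
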