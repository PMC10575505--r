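#' Published provincial reference values
#'
#' The provincial surveillance analysis this package operationalises was run
#' on access-restricted administrative databases; its row-level data cannot
#' be redistributed.  What *can* be checked at desk scale is the arithmetic
#' of the published summary tables.  These loaders return the published
#' age-standardised annual prescribing rates per 1000 (with prescription
#' counts) by category and province, and the published cohort counts
#' (episodes, prescribed episodes, sex and age-band counts), bundled as
#' plain CSV under `inst/extdata/`.
#'
#' @return a tibble; see the CSV headers for columns.
#' @export
published_rates <- function() {
  readr::read_csv(system.file("extdata", "published_rates.csv", package = "capquality"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_rates
#' @export
published_cohort <- function() {
  readr::read_csv(system.file("extdata", "published_cohort.csv", package = "capquality"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Recompute the published percentage-difference column
#'
#' Applies [pct_difference()] to the published first- and final-year rates
#' for every category/province, reproducing the published Delta column.
#'
#' @param rates a table shaped like [published_rates()].
#' @return tibble with `category`, `province`, `rate_start`, `rate_end`,
#'   `delta`.
#' @export
recompute_published_deltas <- function(rates = published_rates()) {
  y0 <- min(rates$year)
  y1 <- max(rates$year)
  start <- rates[rates$year == y0, c("category", "province", "rate_per_1000")]
  end <- rates[rates$year == y1, c("category", "province", "rate_per_1000")]
  out <- dplyr::inner_join(start, end, by = c("category", "province"),
                           suffix = c("_start", "_end"))
  out$delta <- pct_difference(out$rate_per_1000_start, out$rate_per_1000_end)
  names(out)[names(out) == "rate_per_1000_start"] <- "rate_start"
  names(out)[names(out) == "rate_per_1000_end"] <- "rate_end"
  out
}
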