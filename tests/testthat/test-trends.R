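test_that("rates per 1000 handle crude and age-standardised forms", {
  expect_equal(rate_per_1000(100, 10000), 10)
  # homogeneous band rates standardise to themselves
  expect_equal(rate_per_1000(c(5, 10), c(500, 1000), c(0.5, 0.5)), 10)
  # weighted combination of band rates 10 and 20 per 1000
  expect_equal(rate_per_1000(c(10, 20), c(1000, 1000), c(0.6, 0.4)), 14)
  expect_error(rate_per_1000(5, 0), "zero population")
  expect_error(rate_per_1000(c(1, 1), c(10, 10), c(0.5, 0.4)), "sum to 1")
})

test_that("percentage differences reproduce the published Delta arithmetic", {
  expect_equal(pct_difference(2.16, 6.93), 2.21)
  expect_equal(pct_difference(159.92, 127.80), -0.20)
  expect_equal(pct_difference(3.7, 3.7), 0)
  expect_true(is.na(pct_difference(0, 5)))
})

test_that("the two-cell Poisson fit equals the closed-form rate ratio", {
  d <- tibble::tibble(year = c(2014, 2018), count = c(50, 100),
                      population = c(1000, 1000))
  fit <- poisson_trend(d)
  expect_equal(fit$rate_ratio, 2, tolerance = 1e-8)
  expect_equal(fit$reference_year, 2014)
  expect_equal(fit$comparison_year, 2018)
  expect_true(fit$ci_low < 2 && fit$ci_high > 2)

  # random two-year instances: MLE is the ratio of offset-adjusted rates
  set.seed(88)
  for (rep in 1:30) {
    d <- tibble::tibble(year = 2014:2015,
                        count = sample(5:500, 2),
                        population = sample(1000:9000, 2))
    fit <- poisson_trend(d)
    closed <- (d$count[2] / d$population[2]) / (d$count[1] / d$population[1])
    expect_equal(fit$rate_ratio, closed, tolerance = 1e-8)
  }
})

test_that("the null model returns a unit rate ratio with p near 1", {
  d <- tibble::tibble(year = 2014:2018, count = 40, population = 1000)
  fit <- poisson_trend(d)
  expect_equal(fit$rate_ratio, 1, tolerance = 1e-8)
  expect_gt(fit$p_value, 0.99)
  expect_false(fit$continuity_corrected)
})

test_that("a zero reference-year count triggers the flagged continuity correction", {
  d <- tibble::tibble(year = 2014:2016, count = c(0, 8, 12), population = 1000)
  fit <- poisson_trend(d)
  expect_true(fit$continuity_corrected)
  expect_equal(fit$rate_ratio, 12.5 / 0.5, tolerance = 1e-6)
  expect_true(is.finite(fit$ci_low) && is.finite(fit$ci_high))
})

test_that("multi-year categorical fits recover per-year rate ratios", {
  set.seed(11)
  pop <- c(2000, 2500, 3000)
  lam <- c(0.02, 0.03, 0.05)
  d <- tibble::tibble(year = 2014:2016, count = rpois(3, lam * pop), population = pop)
  fit <- poisson_trend(d, comparison_year = 2016)
  closed <- (d$count[3] / d$population[3]) / (d$count[1] / d$population[1])
  expect_equal(fit$rate_ratio, closed, tolerance = 1e-8)   # saturated model
})

test_that("duration frequencies tabulate counts, proportions and the mode", {
  linked <- tibble::tibble(
    agent = "amoxicillin", atc_code = "J01CA04",
    avg_daily_dose_mg = 2500,
    duration_days = c(5, 7, 7, 7, 10, 10)
  )
  tab <- duration_frequency(linked, suppress = FALSE)
  expect_equal(tab$duration_days, c(5, 7, 10))
  expect_equal(tab$n, c(1L, 3L, 2L))
  expect_equal(tab$proportion, c(1 / 6, 1 / 2, 1 / 3))
  expect_equal(tab$duration_days[which.max(tab$n)], 7)
  # non-first-line rows drop out under first_line_only
  linked2 <- dplyr::bind_rows(linked,
    tibble::tibble(agent = "azithromycin", atc_code = "J01FA10",
                   avg_daily_dose_mg = 250, duration_days = 3))
  expect_equal(sum(duration_frequency(linked2, suppress = FALSE)$n), 6)
  # suppression masks small cells in the reported table
  sup <- duration_frequency(linked, suppress = TRUE)
  expect_true(all(sup$n == "<6"))
})

test_that("ATC-class breakdowns give per-category proportions summing to one", {
  expect_equal(atc_major_class(c("J01FA10", "J01MA12", "J01AA02", "J01CR02", "J01XE01")),
               c("macrolides", "fluoroquinolones", "tetracyclines",
                 "other_beta_lactams", "other"))
  cl <- tibble::tibble(
    category = factor(rep("not_recommended", 4),
                      levels = c("clinically_appropriate", "not_recommended")),
    atc_code = c("J01FA10", "J01FA09", "J01FA10", "J01MA12")
  )
  tab <- atc_class_breakdown(cl, suppress = FALSE)
  expect_equal(tab$proportion[tab$atc_class == "macrolides"], 0.75)
  expect_equal(tab$proportion[tab$atc_class == "fluoroquinolones"], 0.25)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-9)

  single <- tibble::tibble(category = "clinically_appropriate",
                           atc_code = rep("J01FA10", 8))
  tab2 <- atc_class_breakdown(single, suppress = FALSE)
  expect_equal(tab2$proportion, 1)
})

test_that("the generated not-recommended class mix is recovered through the pipeline", {
  # a cohort with no justifications makes every prescription not recommended,
  # so the configured 42% macrolide share is estimable with a large n
  prev <- sim_config()$comorbidity_prevalence * 0
  meds <- sim_config()$medication_prevalence * 0
  cfg <- sim_config(seed = 61, n_patients = 3000,
                    comorbidity_prevalence = prev, medication_prevalence = meds,
                    category_mix = c(guideline_adherent = 0,
                                     clinically_appropriate = 0,
                                     effective_but_unnecessary = 0,
                                     undertreatment = 0, not_recommended = 1),
                    decoy_rate = 0)
  res <- run_pipeline(pipeline_config(simulate = cfg))
  expect_true(all(res$classified$category == "not_recommended"))
  tab <- atc_class_breakdown(res$classified, suppress = FALSE)
  p_hat <- tab$proportion[tab$atc_class == "macrolides"]
  n <- sum(tab$n)
  expect_lt(abs(p_hat - 0.42), 3 * sqrt(0.42 * 0.58 / n))
})
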