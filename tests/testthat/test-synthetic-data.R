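test_that("config validation names the offending field", {
  expect_error(sim_config(prescribe_probability = 1.5), "prescribe_probability")
  expect_error(sim_config(age_min = 60), "age_min")
  expect_error(sim_config(category_mix = c(guideline_adherent = 1)), "category_mix")
  expect_error(sim_config(duration_pmf = c(`40` = 1)), "duration_pmf")
  expect_error(sim_config(visit_pmf = c(`1` = 0.5)), "visit_pmf")
})

test_that("an empty cohort yields empty tables with full headers", {
  cfg <- sim_config(n_patients = 0)
  reg <- generate_cohort(cfg)
  expect_equal(nrow(reg), 0)
  expect_named(reg, c("patient_id", "age", "sex", "province", "long_term_care",
                      "income_quintile", "rural"))
  claims <- generate_claims(cfg, reg)
  expect_equal(nrow(claims$visits), 0)
  expect_equal(nrow(claims$dispensations), 0)
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 1, n_patients = 400)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ca <- generate_claims(cfg, a)
  cb <- generate_claims(cfg, b)
  expect_identical(ca, cb)
  # and through the file layer
  d1 <- file.path(tempdir(), "sim-a"); d2 <- file.path(tempdir(), "sim-b")
  simulate_claims(cfg, d1); simulate_claims(cfg, d2)
  for (f in c("registry.csv", "visits.csv", "dispensations.csv",
              "admissions.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("cohort demographics follow the configured model", {
  cfg <- sim_config(seed = 5, n_patients = 100000, prop_female = 0.55)
  reg <- generate_cohort(cfg)
  expect_true(all(reg$age >= 65))
  # observed female share within 3 binomial sd of the target
  p_hat <- mean(reg$sex == "F")
  expect_lt(abs(p_hat - 0.55), 3 * sqrt(0.55 * 0.45 / 100000))
  # truncated normal: mean near the configured centre
  expect_equal(mean(reg$age), 78, tolerance = 0.02)
})

test_that("prescribe probability zero produces no antibiotic dispensations", {
  cfg <- sim_config(seed = 3, n_patients = 300, prescribe_probability = 0,
                    medication_prevalence = c(interacting_drugs = 0,
                                              immunosuppressive_meds = 0))
  claims <- generate_claims(cfg, generate_cohort(cfg))
  expect_equal(nrow(claims$dispensations), 0)
  # with medication classes back on, only non-antibiotic rows appear
  cfg2 <- sim_config(seed = 3, n_patients = 300, prescribe_probability = 0)
  claims2 <- generate_claims(cfg2, generate_cohort(cfg2))
  expect_false(any(startsWith(claims2$dispensations$atc_code, "J01")))
})

test_that("a pure guideline-adherent mix emits only concordant first-line regimens", {
  cfg <- sim_config(seed = 9, n_patients = 1500, decoy_rate = 0,
                    category_mix = c(guideline_adherent = 1,
                                     clinically_appropriate = 0,
                                     effective_but_unnecessary = 0,
                                     undertreatment = 0, not_recommended = 0))
  claims <- generate_claims(cfg, generate_cohort(cfg))
  rx <- claims$dispensations[startsWith(claims$dispensations$atc_code, "J01"), ]
  expect_gt(nrow(rx), 100)
  rules <- default_rules()
  fl <- rules[rules$is_first_line, ]
  expect_true(all(rx$agent %in% fl$agent))
  conc <- assess_concordance(
    tibble::tibble(agent = rx$agent, atc_code = rx$atc_code,
                   avg_daily_dose_mg = rx$strength_mg * rx$quantity / rx$days_supply,
                   duration_days = rx$days_supply), rules)
  expect_true(all(conc$dose_direction == "within"))
  expect_true(all(rx$days_supply == 5))
})

test_that("generated structure honours the episode and window guarantees", {
  cfg <- sim_config(seed = 21, n_patients = 800)
  claims <- generate_claims(cfg, generate_cohort(cfg))
  tr <- claims$truth$episodes
  # non-chronic episodes span at most 30 days; chronic ones exceed it
  expect_true(all(tr$span_days[!tr$chronic] <= 30))
  expect_true(all(tr$span_days[tr$chronic] > 30))
  # intended first dispensations sit inside their linkage window
  rx <- dplyr::inner_join(tr[tr$prescribed, ],
                          claims$dispensations, by = "record_id")
  off <- as.integer(rx$dispense_date - rx$index_date)
  expect_true(all(off >= 0 & off <= rx$span_days + 5))
  # admissions begin within 5 days of the episode end
  hosp <- tr[tr$hospitalized, ]
  adm <- dplyr::inner_join(hosp, claims$admissions, by = "patient_id",
                           relationship = "many-to-many")
  adm <- adm[adm$admission_date >= adm$index_date, ]
  expect_true(all(tapply(as.integer(adm$admission_date - adm$end_date),
                         adm$patient_id, min) <= 5))
})

test_that("empirical prescribe fraction and duration ordering match the config", {
  cfg <- sim_config(seed = 13, n_patients = 4000)
  claims <- generate_claims(cfg, generate_cohort(cfg))
  tr <- claims$truth$episodes
  p_hat <- mean(tr$prescribed)
  se <- sqrt(0.49 * 0.51 / nrow(tr))
  expect_lt(abs(p_hat - 0.49), 3.5 * se)
  # dispensed durations of non-first-line agents follow the pmf: 7 > 10 > 5
  nfl <- claims$dispensations[claims$dispensations$atc_code %in%
                                c("J01FA10", "J01FA09", "J01MA12", "J01MA14",
                                  "J01DC02", "J01EE01"), ]
  nfl <- nfl[nfl$record_id <= sum(tr$prescribed), ]   # intended records only
  tab <- sort(table(nfl$days_supply), decreasing = TRUE)
  expect_equal(names(tab), c("7", "10", "5"))
})

test_that("unknown patient ids in the registry are rejected", {
  cfg <- sim_config(n_patients = 10)
  reg <- generate_cohort(cfg)
  reg2 <- dplyr::bind_rows(reg, reg[1, ])
  expect_error(generate_claims(cfg, reg2), "duplicated patient ids")
})
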