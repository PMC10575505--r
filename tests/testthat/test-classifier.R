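origin <- as.Date("2014-01-01")

test_that("Charlson scores sum the shipped weights", {
  w <- default_charlson_weights()
  expect_equal(compute_charlson(setNames(rep(FALSE, length(w)), names(w))), 0L)
  expect_equal(
    compute_charlson(c(myocardial_infarction = TRUE, diabetes = TRUE, cancer = TRUE)),
    4L
  )
  expect_equal(compute_charlson(setNames(rep(TRUE, length(w)), names(w))),
               as.integer(sum(w)))
  expect_error(compute_charlson(c(gout = TRUE)), "absent from Charlson weight table")
  # data-frame input scores row-wise
  df <- tibble::tibble(myocardial_infarction = c(TRUE, FALSE), cancer = c(TRUE, TRUE))
  expect_equal(compute_charlson(df), c(3L, 2L))
})

test_that("justification profiles scan the lookback window across record types", {
  none <- build_justifications("p1", origin + 400)
  expect_false(none$has_any_justification)
  expect_equal(none$charlson_score, 0L)

  # COPD-coded visit 100 days before index is inside the 365-day lookback
  copd_visit <- make_visits(300, code = "4919")   # index at day 400
  j <- build_justifications("p1", origin + 400, visits = copd_visit)
  expect_true(j$copd)
  expect_true(j$has_any_justification)
  expect_equal(j$charlson_score, 1L)
  # the same record 400 days before index is out of window
  j2 <- build_justifications("p1", origin + 700, visits = copd_visit)
  expect_false(j2$copd)
  # records after index never count
  j3 <- build_justifications("p1", origin + 200, visits = copd_visit)
  expect_false(j3$copd)

  # hospital ICD-10 path: an admission coded I50 flags heart failure
  adm <- tibble::tibble(patient_id = "p1", admission_date = origin + 350,
                        discharge_date = origin + 355, diagnosis_codes = "I50;J18")
  j4 <- build_justifications("p1", origin + 400, admissions = adm)
  expect_true(j4$congestive_heart_failure)

  # dispensation path: an immunosuppressant ATC flags the medication class
  med <- make_dispensation(1, "p1", origin + 380, agent = "mycophenolate",
                           atc = "L04AA06")
  j5 <- build_justifications("p1", origin + 400, dispensations = med)
  expect_true(j5$immunosuppressive_meds)
  expect_true(j5$has_any_justification)

  # a moderate/severe Charlson score is itself a justification
  v <- dplyr::bind_rows(make_visits(390, code = "4280"), make_visits(391, code = "1629"))
  j6 <- build_justifications("p1", origin + 400, visits = v)
  expect_equal(j6$charlson_score, 3L)
  expect_true(j6$charlson_moderate_severe)
})

test_that("per-condition lookback overrides are honoured", {
  copd_visit <- make_visits(0, code = "4919")
  lb <- c(copd = 30, .default = 365)
  j <- build_justifications("p1", origin + 100, visits = copd_visit, lookback_days = lb)
  expect_false(j$copd)
  j2 <- build_justifications("p1", origin + 20, visits = copd_visit, lookback_days = lb)
  expect_true(j2$copd)
})

test_that("the decision table classifies the worked examples", {
  # first-line, fully concordant, no justifications
  ga <- classify_one(TRUE, "within", "within", FALSE, FALSE)
  expect_equal(ga$category, "guideline_adherent")

  # opposing deviations: subtherapeutic dose with excess duration
  ut <- classify_one(TRUE, "below", "above", FALSE, FALSE)
  expect_equal(ut$category, "undertreatment")

  # the same prescription with renal dysfunction is reclassified
  ca <- classify_one(TRUE, "below", "above", TRUE, TRUE)
  expect_equal(ca$category, "clinically_appropriate")
  expect_true(ca$reclassified_from_undertreatment)

  # non-first-line splits on justification
  expect_equal(classify_one(FALSE, NA, NA, TRUE, FALSE)$category, "clinically_appropriate")
  expect_equal(classify_one(FALSE, NA, NA, FALSE, FALSE)$category, "not_recommended")

  # excess on one axis, none below
  expect_equal(classify_one(TRUE, "within", "above", TRUE, FALSE)$category,
               "effective_but_unnecessary")
})

test_that("the classifier matches the brute-force oracle on all 72 grid cells", {
  grid <- expand.grid(
    first_line = c(TRUE, FALSE),
    dose_dir = c("below", "within", "above"),
    dur_dir = c("below", "within", "above"),
    justified = c(TRUE, FALSE),
    ckd = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(grid), 72)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- classify_one(g$first_line, g$dose_dir, g$dur_dir, g$justified, g$ckd)
    want <- oracle_category(g$first_line, g$dose_dir, g$dur_dir, g$justified, g$ckd)
    expect_equal(got$category, want,
                 info = paste(unlist(g), collapse = "/"))
    expect_true(got$category %in% c("guideline_adherent", "clinically_appropriate",
                                    "effective_but_unnecessary", "undertreatment",
                                    "not_recommended"))
  }
})

test_that("vectorised classification is exhaustive and exclusive", {
  ep <- build_episodes(dplyr::bind_rows(lapply(1:6, function(i) {
    make_visits(0, patient_id = sprintf("p%d", i))
  })))
  d <- dplyr::bind_rows(
    make_dispensation(1, "p1", origin, "amoxicillin", "J01CA04", 500, 20, 5),      # adherent
    make_dispensation(2, "p2", origin, "amoxicillin", "J01CA04", 500, 15, 5),      # dose below
    make_dispensation(3, "p3", origin, "azithromycin", "J01FA10", 250, 5, 5),
    make_dispensation(4, "p4", origin, "azithromycin", "J01FA10", 250, 5, 5),
    make_dispensation(5, "p5", origin, "amoxicillin", "J01CA04", 500, 28, 7),      # duration above
    make_dispensation(6, "p6", origin, "nitrofurantoin", "J01XE01", 100, 10, 5)    # unknown agent
  )
  linked <- link_prescriptions(ep, d)
  just <- dplyr::bind_rows(
    make_justification(linked$episode_id[linked$patient_id == "p1"]),
    make_justification(linked$episode_id[linked$patient_id == "p2"], ckd = TRUE),
    make_justification(linked$episode_id[linked$patient_id == "p3"], justified = TRUE),
    make_justification(linked$episode_id[linked$patient_id == "p4"]),
    make_justification(linked$episode_id[linked$patient_id == "p5"]),
    make_justification(linked$episode_id[linked$patient_id == "p6"])
  )
  got <- classify_prescriptions(linked, just)
  expect_equal(nrow(got), 6)
  expect_false(anyNA(got$category))
  by_pat <- setNames(as.character(got$category), got$patient_id)
  expect_equal(unname(by_pat[c("p1", "p2", "p3", "p4", "p5", "p6")]),
               c("guideline_adherent", "clinically_appropriate",
                 "clinically_appropriate", "not_recommended",
                 "effective_but_unnecessary", "not_recommended"))
  expect_true(got$reclassified_from_undertreatment[got$patient_id == "p2"])
  # category counts partition the linked prescriptions
  expect_equal(sum(table(got$category)), nrow(got))
})
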