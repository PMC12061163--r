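test_that("eligibility and caseness criteria behave on hand-built patients", {
  cohort <- tiny_cohort()
  labels <- build_study_population(cohort)
  lab <- function(id) labels[labels$patient_id == id, ]

  # T01: inclusion diagnosis + recent medication -> case
  expect_true(lab("T01")$is_case)
  # T02: aged 17 at index with qualifying records -> not in study population
  expect_false(lab("T02")$in_study_population)
  # T03: registered less than a year -> excluded
  expect_false(lab("T03")$in_study_population)
  # T04: exclusion diagnosis dominates despite qualifying records
  expect_false(lab("T04")$in_study_population)
  expect_false(lab("T04")$is_case)
  expect_true(lab("T04")$has_inclusion_diagnosis)
  # T06: inclusion diagnosis 12y before index, last prescription 11y before
  # index -> no recent record at all, so not even in the study population
  expect_true(lab("T06")$has_inclusion_diagnosis)
  expect_false(lab("T06")$has_recent_medication)
  expect_false(lab("T06")$in_study_population)
  expect_false(lab("T06")$is_case)
  # T07: generic psychiatric codes + recent medication -> control in pop
  expect_true(lab("T07")$in_study_population)
  expect_false(lab("T07")$is_case)
  # T08: no records -> out
  expect_false(lab("T08")$in_study_population)
})

test_that("an old inclusion diagnosis with a recent prescription is a case", {
  cohort <- tiny_cohort()
  # give T06 (inclusion dx in 2009) a prescription 2 years before index
  cohort$prescriptions <- rbind(
    cohort$prescriptions,
    data.table::data.table(patient_id = "T06", name = "Sertraline",
                           class = "antidepressant",
                           date = as.Date("2019-12-01")))
  labels <- build_study_population(cohort)
  expect_true(labels[labels$patient_id == "T06", ]$is_case)
})

test_that("membership matches an independent per-patient predicate oracle", {
  cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 21))
  labels <- build_study_population(cohort)
  idx <- as.Date("2021-12-31")
  med_names <- medications_of_interest()$name
  dx <- as.data.frame(cohort$diagnoses)
  rx <- as.data.frame(cohort$prescriptions)
  for (i in seq_len(nrow(cohort$patients))) {
    pat <- as.data.frame(cohort$patients)[i, ]
    o <- oracle_labels_one(pat, dx, rx, idx, med_names)
    row <- labels[labels$patient_id == pat$patient_id, ]
    expect_equal(row$in_study_population, o$in_pop, info = pat$patient_id)
    expect_equal(row$is_case, o$is_case, info = pat$patient_id)
  }
})

test_that("caseness is monotone in qualifying prescriptions and exclusion dominates", {
  cohort <- generate_cohort(cohort_config(n_patients = 400, seed = 31))
  labels <- build_study_population(cohort)
  cases <- labels$patient_id[labels$is_case]
  # add one more qualifying prescription to every case: all stay cases
  extra <- data.table::data.table(patient_id = cases, name = "Citalopram",
                                  class = "antidepressant",
                                  date = as.Date("2021-06-01"))
  cohort$prescriptions <- rbind(cohort$prescriptions, extra)
  labels2 <- build_study_population(cohort)
  expect_true(all(labels2$is_case[labels2$patient_id %in% cases]))
  # adding an exclusion code removes a case regardless of other records
  if (length(cases)) {
    cohort$diagnoses <- rbind(
      cohort$diagnoses,
      data.table::data.table(patient_id = cases[1], code = "EXC_BIP",
                             date = as.Date("2020-01-01")))
    labels3 <- build_study_population(cohort)
    row <- labels3[labels3$patient_id == cases[1], ]
    expect_false(row$in_study_population)
    expect_false(row$is_case)
  }
})

test_that("cases are nested in the study population with weakly decreasing counts", {
  cohort <- generate_cohort(cohort_config(n_patients = 3000, seed = 13))
  labels <- build_study_population(cohort)
  expect_true(all(labels$is_case <= labels$in_study_population))
  n_total <- nrow(labels)
  n_study <- sum(labels$in_study_population)
  n_case <- sum(labels$is_case)
  expect_true(n_total >= n_study && n_study >= n_case)
})

test_that("missing demographics exclude the patient with a warning", {
  cohort <- tiny_cohort()
  cohort$patients$birth_year[1] <- NA
  expect_warning(labels <- build_study_population(cohort), "missing")
  expect_false(labels$in_study_population[1])
  expect_equal(attr(labels, "n_missing_demographics"), 1L)
})

test_that("summarize_caseness percentages equal a brute-force recount", {
  set.seed(77)
  n <- 5000
  labels <- data.table::data.table(
    patient_id = sprintf("R%05d", 1:n),
    in_study_population = runif(n) < 0.2,
    has_inclusion_diagnosis = runif(n) < 0.05,
    has_recent_medication = runif(n) < 0.5,
    has_exclusion_diagnosis = FALSE
  )
  labels$is_case <- labels$in_study_population &
    labels$has_inclusion_diagnosis & labels$has_recent_medication
  s <- summarize_caseness(labels, disclosure = FALSE)
  n_study <- sum(labels$in_study_population)
  expect_equal(s$percent[s$quantity == "study_population"],
               round(100 * n_study / n, 1))
  expect_equal(s$percent[s$quantity == "caseness"],
               round(100 * sum(labels$is_case) / n_study, 1))
  # with disclosure control every published count is a multiple of ten
  s2 <- summarize_caseness(labels, disclosure = TRUE)
  expect_true(all(is.na(s2$count) | s2$count %% 10 == 0))
})
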