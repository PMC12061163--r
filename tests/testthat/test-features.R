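test_that("binary code features: absence, idempotence, closure", {
  cohort <- tiny_cohort()
  vocab <- default_vocabulary()
  pids <- cohort$patients$patient_id
  f <- extract_binary_code_features(cohort, vocab, patient_ids = pids)
  # T08 has no diagnosis events: every code feature 0
  expect_true(all(f[f$patient_id == "T08", -1] == 0))
  # T07 has PSY_DEP recorded twice: still 1, not 2
  expect_equal(f[f$patient_id == "T07", ][["code_PSY_DEP"]], 1L)
  # closure: T05 has the child PSY_GAD; the parent anxiety feature fires
  expect_equal(f[f$patient_id == "T05", ][["code_PSY_ANX"]], 1L)
  expect_equal(f[f$patient_id == "T05", ][["code_PSY_GAD"]], 1L)
  # with closure off the parent feature stays 0
  f2 <- extract_binary_code_features(cohort, vocab, codes = "PSY_ANX",
                                     closure = FALSE, patient_ids = pids)
  expect_equal(f2[f2$patient_id == "T05", ][["code_PSY_ANX"]], 0L)
  # oracle: closure feature equals membership of the event code in the
  # parent's descendant closure
  closure <- code_closure(vocab, "PSY_ANX")
  for (id in pids) {
    codes_i <- cohort$diagnoses[cohort$diagnoses$patient_id == id, ][["code"]]
    expect_equal(f[f$patient_id == id, ][["code_PSY_ANX"]],
                 as.integer(any(codes_i %in% closure)), info = id)
  }
})

test_that("distinct psychiatric diagnosis count matches a brute-force scan", {
  vocab <- default_vocabulary()
  # same code on 5 dates counts once; no psychiatric codes counts zero
  dx <- data.table::data.table(
    patient_id = rep("A", 5), code = "PSY_OCD",
    date = as.Date("2020-01-01") + 1:5)
  expect_equal(count_unique_psychiatric_diagnoses(dx, vocab, c("A", "B")),
               c(1L, 0L))
  # random streams vs brute-force set oracle
  set.seed(55)
  cohort <- generate_cohort(cohort_config(n_patients = 150, seed = 55))
  pids <- cohort$patients$patient_id
  got <- count_unique_psychiatric_diagnoses(cohort$diagnoses, vocab, pids)
  psy <- vocab$codes[vocab$codes$role %in% c("psychiatric", "inclusion"),
                     ][["code"]]
  dxdf <- as.data.frame(cohort$diagnoses)
  want <- vapply(pids, function(id)
    length(unique(dxdf$code[dxdf$patient_id == id & dxdf$code %in% psy])),
    integer(1))
  expect_equal(got, unname(want))
})

test_that("aborted regime counting matches a brute-force grouping oracle", {
  idx <- as.Date("2021-12-31")
  mk <- function(dates, name = "Sertraline") data.table::data.table(
    patient_id = "A", name = name, class = "antidepressant",
    date = as.Date(dates))
  # a single prescription 3 years before the index is one aborted regime
  expect_equal(count_aborted_regimes(mk("2018-06-01"), index_date = idx,
                                     patient_ids = "A"), 1L)
  # monthly prescriptions for 2 years form one long (not aborted) regime
  monthly <- seq(as.Date("2019-06-01"), by = "month", length.out = 24)
  expect_equal(count_aborted_regimes(mk(monthly), index_date = idx,
                                     patient_ids = "A"), 0L)
  # a short regime still open at the index is not aborted
  expect_equal(count_aborted_regimes(mk(idx - 10), index_date = idx,
                                     patient_ids = "A"), 0L)
  # randomized dates across two medications vs the oracle
  set.seed(66)
  for (rep in 1:25) {
    d1 <- sort(sample(seq(idx - 3000, idx, by = "day"),
                      sample(1:12, 1)))
    d2 <- sort(sample(seq(idx - 3000, idx, by = "day"),
                      sample(0:8, 1)))
    rx <- rbind(mk(d1, "Sertraline"), mk(d2, "Fluoxetine"))
    expect_equal(
      count_aborted_regimes(rx, index_date = idx, patient_ids = "A"),
      oracle_aborted(list(d1, d2), idx))
  }
})

test_that("attendance series bins match brute-force date filtering", {
  cohort <- tiny_cohort()
  s <- build_attendance_series(cohort, n_years = 5, patient_ids = "T01")
  # 12 appointments in 2021, all attended: DNA counts all zero
  expect_true(all(s$n_dna == 0))
  expect_equal(sum(s$n_appointments), 12L)
  expect_equal(s[s$year == 2021, ][["n_appointments"]], rep(1L, 12))
  # bins are contiguous calendar months
  mid <- s$year * 12 + s$month
  expect_equal(diff(mid), rep(1L, nrow(s) - 1))
  # random events: bin sums equal brute-force filtering
  set.seed(44)
  cohort2 <- generate_cohort(cohort_config(n_patients = 30, seed = 44))
  s2 <- build_attendance_series(cohort2, n_years = 5)
  ap <- as.data.frame(cohort2$appointments)
  idx <- as.Date("2021-12-31")
  win <- idx - round(5 * 365.25) + 1
  for (row in sample(nrow(s2), 50)) {
    r <- s2[row, ]
    m0 <- as.Date(sprintf("%d-%02d-01", r$year, r$month))
    m1 <- seq(m0, by = "month", length.out = 2)[2] - 1
    sel <- ap$patient_id == r$patient_id & ap$date >= max(m0, win) &
      ap$date <= min(m1, idx)
    expect_equal(r$n_appointments, sum(sel))
    expect_equal(r$n_dna, sum(ap$status[sel] == "DNA"))
  }
})

test_that("feature extraction is invariant to event-row shuffling", {
  cohort <- generate_cohort(cohort_config(n_patients = 250, seed = 8))
  labels <- build_study_population(cohort)
  fm1 <- build_feature_matrix(cohort, labels)
  set.seed(1)
  shuffled <- cohort
  for (tab in c("diagnoses", "prescriptions", "appointments", "referrals")) {
    shuffled[[tab]] <- shuffled[[tab]][sample(nrow(shuffled[[tab]])), ]
  }
  fm2 <- build_feature_matrix(shuffled, labels)
  expect_equal(fm1$features, fm2$features)
  expect_equal(fm1$meta, fm2$meta)
})

test_that("feature metadata partitions features across the eight families", {
  cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 12))
  labels <- build_study_population(cohort)
  fm <- build_feature_matrix(cohort, labels)
  expect_false(anyDuplicated(fm$meta$feature_id) > 0)
  expect_setequal(unique(fm$meta$family), names(mhscreen:::family_order()))
  expect_true(all(fm$meta$value_type %in% c("binary", "count", "continuous")))
  expect_true(all(fm$meta$provenance %in%
                    c("fs_literature", "fs_interviews", "fs_clinician")))
  # binary features are never missing
  bin <- fm$meta$feature_id[fm$meta$value_type == "binary"]
  for (b in bin) expect_false(anyNA(fm$features[[b]]), info = b)
})
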