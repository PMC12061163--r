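#' Feature extraction parameters
#'
#' Tunable parameters of the component-feature extractors. None of these
#' have field-standard values for primary-care non-attendance series; the
#' defaults are documented choices, all overridable.
#'
#' @param attendance_years length of the attendance window before the index
#'   date used for the monthly non-attendance series (years).
#' @param sampen_m,sampen_r_factor sample-entropy embedding length and
#'   tolerance factor (`r = factor * sd(series)`).
#' @param ai_history_months,ai_recent_months active-information window:
#'   number of sliding windows and history-pattern length (months).
#' @param regime_gap_days maximum gap between consecutive prescriptions of
#'   the same medication for them to belong to one regime.
#' @param regime_min_duration_days a regime shorter than this is "aborted"
#'   (12 weeks, a typical minimum course).
#' @param recent_code_years window for "recent" mental-health coding
#'   activity features.
#' @param medication_window_years lookback window for prescription-presence
#'   features (aligned with the caseness medication criterion).
#' @param age_split_years age split between antecedent (before) and
#'   concurrent (after) code features.
#' @param count_discrete_max_levels count features with at most this many
#'   distinct observed values are treated as discrete by the MI ranking;
#'   beyond it the nearest-neighbour mixed estimator is used.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(attendance_years = 5L,
                           sampen_m = 2L,
                           sampen_r_factor = 0.2,
                           ai_history_months = 12L,
                           ai_recent_months = 3L,
                           regime_gap_days = 90L,
                           regime_min_duration_days = 84L,
                           recent_code_years = 2L,
                           medication_window_years = 10,
                           age_split_years = 30L,
                           count_discrete_max_levels = 30L) {
  structure(as.list(environment()), class = "feature_params")
}

# 0/1 matrix of code presence for (patient, code) event pairs.
# closure = TRUE activates a feature when the event code is the feature code
# or any of its descendants.
.binary_code_matrix <- function(events, vocab, feature_codes, patient_ids,
                                closure = TRUE) {
  out <- data.table(patient_id = patient_ids)
  if (!length(feature_codes)) return(out)
  act <- rbindlist(lapply(feature_codes, function(fc) {
    members <- if (closure) code_closure(vocab, fc) else fc
    data.table(code = members, feature_code = fc)
  }))
  ev <- unique(as.data.table(events)[, .(patient_id, code)])
  hits <- merge(ev, act, by = "code", allow.cartesian = TRUE)
  for (fc in feature_codes) {
    col <- paste0("code_", fc)
    out[, (col) := as.integer(patient_id %in% hits[feature_code == fc, patient_id])]
  }
  out
}

#' Binary code-presence features
#'
#' One 0/1 column per requested code: 1 iff the patient has at least one
#' diagnosis event with that code (or, when `closure = TRUE`, any of its
#' descendants). Recording the same code repeatedly does not change the
#' value.
#'
#' @param cohort an `mh_cohort`.
#' @param vocab a [code_vocabulary()].
#' @param codes feature codes; default all diagnosis-role codes that are
#'   not part of the caseness definition (inclusion/exclusion lists are not
#'   features).
#' @param closure search descendants of each feature code too?
#' @param patient_ids patients to evaluate (default: all in the cohort).
#' @return data.table with `patient_id` and one `code_<id>` column per
#'   feature code.
#' @export
extract_binary_code_features <- function(cohort, vocab = default_vocabulary(),
                                         codes = NULL, closure = TRUE,
                                         patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- cohort$patients$patient_id
  if (is.null(codes)) {
    codes <- vocab$codes[role %in% c("psychiatric", "antecedent",
                                     "concurrent", "other"), code]
  }
  .binary_code_matrix(cohort$diagnoses, vocab, codes, patient_ids, closure)
}

#' Count of distinct psychiatric diagnoses
#'
#' The number of DISTINCT mental-disorder codes ever recorded for each
#' patient (codes with the `psychiatric` or `inclusion` role; repeat
#' recordings of the same code count once). This is the simple,
#' automatically computable "dose" style feature: under the planted
#' generative model its distribution is stochastically larger in latent
#' cases.
#'
#' @param diagnoses diagnosis events (`patient_id`, `code`, `date`).
#' @param vocab a [code_vocabulary()].
#' @param patient_ids patients to evaluate.
#' @param index_date only events on or before this date are counted.
#' @return integer vector of counts aligned with `patient_ids`.
#' @export
count_unique_psychiatric_diagnoses <- function(diagnoses,
                                               vocab = default_vocabulary(),
                                               patient_ids,
                                               index_date = NULL) {
  psy_codes <- vocab$codes[role %in% c("psychiatric", "inclusion"), code]
  dx <- as.data.table(diagnoses)[code %in% psy_codes]
  if (!is.null(index_date)) dx <- dx[date <= as.Date(index_date)]
  cnt <- dx[, .(n = length(unique(code))), by = patient_id]
  out <- cnt[data.table(patient_id = patient_ids), on = "patient_id"]
  fifelse(is.na(out$n), 0L, out$n)
}

#' Count of aborted medication regimes
#'
#' Prescriptions of each matched medication are grouped into regimes:
#' consecutive issues at most `gap_days` apart belong to the same regime. A
#' regime is "aborted" when its span (first to last issue) is shorter than
#' `min_duration_days` and it is not the patient's final regime still open
#' at the index date (last issue within `gap_days` of the index). Returns
#' the total number of aborted regimes per patient across all medications
#' of the class.
#'
#' @param prescriptions prescription events (`patient_id`, `name`, `date`).
#' @param medications medications-of-interest table (`name`, `class`).
#' @param med_class class to analyse.
#' @param gap_days,min_duration_days regime construction parameters.
#' @param index_date study index date.
#' @param patient_ids patients to evaluate.
#' @return integer vector of counts aligned with `patient_ids`.
#' @export
count_aborted_regimes <- function(prescriptions,
                                  medications = medications_of_interest(),
                                  med_class = "antidepressant",
                                  gap_days = 90L, min_duration_days = 84L,
                                  index_date = as.Date("2021-12-31"),
                                  patient_ids) {
  medications <- as.data.table(medications)
  med_names <- medications[class == med_class, name]
  rx <- as.data.table(prescriptions)[!is.na(date) & date <= as.Date(index_date)]
  matched <- .match_medication_name(rx$name, med_names)
  rx <- rx[!is.na(matched)]
  rx[, med := matched[!is.na(matched)]]
  if (!nrow(rx)) return(rep(0L, length(patient_ids)))
  setorder(rx, patient_id, med, date)
  rx[, regime := cumsum(c(1L, as.integer(diff(as.numeric(date)) > gap_days))),
     by = .(patient_id, med)]
  reg <- rx[, .(span = as.numeric(max(date) - min(date)),
                last = max(date)), by = .(patient_id, med, regime)]
  reg[, open_at_index := as.numeric(as.Date(index_date) - last) <= gap_days]
  reg[, is_last := seq_len(.N) == .N, by = .(patient_id, med)]
  reg[, aborted := span < min_duration_days & !(is_last & open_at_index)]
  cnt <- reg[, .(n = sum(aborted)), by = patient_id]
  out <- cnt[data.table(patient_id = patient_ids), on = "patient_id"]
  fifelse(is.na(out$n), 0L, as.integer(out$n))
}

# map free-text prescription names to canonical medication names by
# case-insensitive substring; returns canonical name or NA
.match_medication_name <- function(names, med_names) {
  lname <- tolower(names)
  out <- rep(NA_character_, length(lname))
  for (m in med_names) {
    hit <- is.na(out) & grepl(tolower(m), lname, fixed = TRUE)
    out[hit] <- m
  }
  out
}

#' Monthly attendance series
#'
#' Contiguous calendar-month bins per patient from
#' `max(registration, index - n_years)` to the index date, with per-month
#' counts of appointments and of non-attended (DNA) appointments.
#'
#' @param cohort an `mh_cohort` (uses `appointments` and `patients`).
#' @param n_years attendance window length.
#' @param index_date study index date.
#' @param patient_ids patients to evaluate.
#' @return data.table with columns `patient_id`, `year`, `month`,
#'   `n_appointments`, `n_dna`, ordered by patient and month.
#' @export
build_attendance_series <- function(cohort, n_years = 5L,
                                    index_date = as.Date("2021-12-31"),
                                    patient_ids = NULL) {
  patients <- as.data.table(cohort$patients)
  if (!is.null(patient_ids)) {
    patients <- patients[patient_id %in% patient_ids]
  }
  index <- as.Date(index_date)
  win_start <- index - round(n_years * 365.25) + 1
  mid <- function(d) as.integer(format(d, "%Y")) * 12L +
    as.integer(format(d, "%m")) - 1L
  start_date <- pmax(patients$registration_date, win_start)
  skel <- patients[, .(patient_id,
                       start_mid = mid(start_date),
                       end_mid = mid(rep(index, .N)))]
  skel <- skel[start_mid <= end_mid]
  grid <- skel[, .(month_id = seq(start_mid, end_mid)), by = patient_id]
  ap <- as.data.table(cohort$appointments)
  ap <- ap[patient_id %in% patients$patient_id & !is.na(date) &
             date >= win_start & date <= index]
  if (nrow(ap)) {
    ap[, month_id := mid(date)]
    agg <- ap[, .(n_appointments = .N, n_dna = sum(status == "DNA")),
              by = .(patient_id, month_id)]
    grid <- merge(grid, agg, by = c("patient_id", "month_id"), all.x = TRUE)
  } else {
    grid[, `:=`(n_appointments = NA_integer_, n_dna = NA_integer_)]
  }
  grid[is.na(n_appointments), n_appointments := 0L]
  grid[is.na(n_dna), n_dna := 0L]
  grid[, `:=`(year = month_id %/% 12L, month = month_id %% 12L + 1L)]
  setorder(grid, patient_id, month_id)
  grid[, .(patient_id, year, month, n_appointments, n_dna)]
}

# per-patient temporal entropy features from the attendance series
.attendance_features <- function(series, params) {
  tot <- series[, .(total_appts = sum(n_appointments)), by = patient_id]
  ydt <- series[, .(dna_year = sum(n_dna), nmonths = .N),
                by = .(patient_id, year)]
  med <- ydt[, .(median_annual_dna = as.numeric(median(dna_year))),
             by = patient_id]
  # quarterly non-attendance entropy over full calendar years
  qdt <- series[, .(q = sum(n_dna)),
                by = .(patient_id, year, quarter = (month - 1L) %/% 3L)]
  full <- ydt[nmonths == 12L, .(patient_id, year)]
  qdt <- qdt[full, on = c("patient_id", "year"), nomatch = NULL]
  ent <- qdt[, .(H = {
    s <- sum(q)
    if (s == 0) 0 else {
      p <- q[q > 0] / s
      -sum(p * log(p)) / log(4)
    }
  }), by = .(patient_id, year)]
  aqe <- ent[, .(avg_quarterly_entropy_nonattendance = mean(H)),
             by = patient_id]
  # series-shape features need the per-patient vectors
  app_l <- split(series$n_appointments, series$patient_id)
  dna_l <- split(series$n_dna, series$patient_id)
  out <- data.table(
    patient_id = names(app_l),
    sample_entropy_appointments = vapply(app_l, function(v)
      sample_entropy(v, m = params$sampen_m,
                     r = params$sampen_r_factor * sd(v)), numeric(1)),
    spectral_entropy_nonattendance = vapply(dna_l, spectral_entropy,
                                            numeric(1)),
    active_information_nonattendance = vapply(dna_l, function(v)
      active_information(as.integer(v > 0),
                         history_months = params$ai_history_months,
                         recent_months = params$ai_recent_months),
      numeric(1))
  )
  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", all = TRUE),
                list(tot, med, aqe, out))
  # no appointments at all: the attendance pattern is unobserved
  cols <- c("median_annual_dna", "sample_entropy_appointments",
            "spectral_entropy_nonattendance",
            "avg_quarterly_entropy_nonattendance",
            "active_information_nonattendance")
  for (cl in cols) out[total_appts == 0L, (cl) := NA_real_]
  out[, total_appts := NULL]
  setcolorder(out, c("patient_id", cols))
  out[]
}

#' Build the component feature matrix
#'
#' Extracts all component features for the requested patients (by default
#' the study population when `labels` is supplied, otherwise every patient)
#' and returns the patients-by-features table together with per-feature
#' metadata (value type, feature family, provenance tag).
#'
#' Families: Antecedent (adversity codes before the age split), Concurrent
#' (concerning codes after it), ServiceUse (coding activity, appointments,
#' referrals volume), Treatment (psychological-therapy referral patterns),
#' Inconsistency (temporal instability of attendance),
#' PatternsOfPrescription (regime patterns of medications of interest),
#' RelevantPrescriptions (presence of specific non-antipsychotic medications
#' of interest), AntipsychoticPrescription (single antipsychotic-presence
#' indicator). Inclusion/exclusion diagnosis codes are part of the caseness
#' definition and are not features.
#'
#' @param cohort an `mh_cohort`.
#' @param labels optional output of [build_study_population()]; when given,
#'   features are extracted for the study population only.
#' @param vocab a [code_vocabulary()].
#' @param params a [feature_params()].
#' @param index_date study index date.
#' @return list with elements `features` (data.table, `patient_id` +
#'   feature columns), `meta` (data.table: `feature_id`, `value_type`,
#'   `family`, `provenance`, `description`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 400, seed = 11))
#' labels <- build_study_population(cohort)
#' fm <- build_feature_matrix(cohort, labels)
#' fm$meta[, .N, by = .(family, value_type)]
#' @export
build_feature_matrix <- function(cohort, labels = NULL,
                                 vocab = default_vocabulary(),
                                 params = feature_params(),
                                 index_date = as.Date("2021-12-31")) {
  index <- as.Date(index_date)
  pids <- if (!is.null(labels)) {
    as.data.table(labels)[in_study_population == TRUE, patient_id]
  } else {
    cohort$patients$patient_id
  }
  patients <- as.data.table(cohort$patients)
  patients <- patients[match(pids, patient_id)]
  dx <- as.data.table(cohort$diagnoses)[patient_id %in% pids & date <= index]
  rx <- as.data.table(cohort$prescriptions)[patient_id %in% pids & date <= index]
  refs <- as.data.table(cohort$referrals)[patient_id %in% pids & date <= index]

  feats <- data.table(patient_id = pids)
  meta <- list()
  add_meta <- function(ids, vtype, fam, prov, desc) {
    meta[[length(meta) + 1L]] <<- data.table(
      feature_id = ids, value_type = vtype, family = fam,
      provenance = prov, description = desc)
  }
  bind <- function(dt) {
    feats <<- merge(feats, dt, by = "patient_id", all.x = TRUE, sort = FALSE)
  }

  ## ServiceUse: psychiatric / other code presence + coding volume --------
  psy_codes <- vocab$codes[role == "psychiatric", code]
  oth_codes <- vocab$codes[role == "other", code]
  bind(.binary_code_matrix(dx, vocab, psy_codes, pids, closure = TRUE))
  add_meta(paste0("code_", psy_codes), "binary", "ServiceUse", "fs_literature",
           paste0("Presence of code ", psy_codes, " or descendant"))
  bind(.binary_code_matrix(dx, vocab, oth_codes, pids, closure = TRUE))
  add_meta(paste0("code_", oth_codes), "binary", "ServiceUse", "fs_clinician",
           paste0("Presence of code ", oth_codes, " or descendant"))

  feats[, n_unique_psychiatric_diagnoses :=
          count_unique_psychiatric_diagnoses(dx, vocab, pids, index)]
  add_meta("n_unique_psychiatric_diagnoses", "count", "ServiceUse",
           "fs_clinician", "Count of distinct psychiatric diagnosis codes")

  recent_start <- index - round(params$recent_code_years * 365.25)
  md_codes <- vocab$codes[role %in% c("psychiatric", "inclusion"), code]
  rec <- dx[code %in% md_codes & date > recent_start,
            .(n = length(unique(code))), by = patient_id]
  feats[, n_recent_mental_codes := .fill0(rec, pids)]
  add_meta("n_recent_mental_codes", "count", "ServiceUse", "fs_literature",
           "Distinct mental-health codes in the recent window")

  ap <- as.data.table(cohort$appointments)[patient_id %in% pids & date <= index]
  yr1 <- ap[date > index - 365, .N, by = patient_id]
  feats[, n_appointments_last_year := .fill0(yr1, pids, "N")]
  add_meta("n_appointments_last_year", "count", "ServiceUse", "fs_clinician",
           "Appointments in the year before the index date")

  nrefs <- refs[, .N, by = patient_id]
  feats[, n_referrals := .fill0(nrefs, pids, "N")]
  add_meta("n_referrals", "count", "ServiceUse", "fs_interviews",
           "Referrals of any type on record")

  ## Antecedent / Concurrent: age-split code features ---------------------
  split_date <- as.Date(paste0(patients$birth_year + params$age_split_years,
                               "-07-01"))
  dx_age <- merge(dx, data.table(patient_id = pids, split_date = split_date),
                  by = "patient_id")
  ant_codes <- vocab$codes[role == "antecedent", code]
  con_codes <- vocab$codes[role == "concurrent", code]
  bind(.binary_code_matrix(dx_age[date < split_date], vocab, ant_codes,
                           pids, closure = TRUE))
  add_meta(paste0("code_", ant_codes), "binary", "Antecedent", "fs_interviews",
           paste0("Code ", ant_codes, " recorded before the age split"))
  bind(.binary_code_matrix(dx_age[date >= split_date], vocab, con_codes,
                           pids, closure = TRUE))
  add_meta(paste0("code_", con_codes), "binary", "Concurrent", "fs_interviews",
           paste0("Code ", con_codes, " recorded after the age split"))

  nant <- dx_age[date < split_date & code %in% ant_codes,
                 .(n = length(unique(code))), by = patient_id]
  feats[, n_antecedent_codes := .fill0(nant, pids)]
  add_meta("n_antecedent_codes", "count", "Antecedent", "fs_interviews",
           "Distinct adversity codes before the age split")
  ncon <- dx_age[date >= split_date & code %in% con_codes,
                 .(n = length(unique(code))), by = patient_id]
  feats[, n_concurrent_codes := .fill0(ncon, pids)]
  add_meta("n_concurrent_codes", "count", "Concurrent", "fs_interviews",
           "Distinct concerning-behaviour codes after the age split")

  ## Treatment: psychological-therapy referral patterns -------------------
  iapt <- refs[type == "REF_IAPT", .N, by = patient_id]
  feats[, n_iapt_referrals := .fill0(iapt, pids, "N")]
  feats[, any_iapt_referral := as.integer(n_iapt_referrals >= 1L)]
  feats[, repeated_iapt_referrals := as.integer(n_iapt_referrals >= 2L)]
  add_meta(c("n_iapt_referrals", "any_iapt_referral", "repeated_iapt_referrals"),
           c("count", "binary", "binary"), "Treatment", "fs_interviews",
           c("Psychological-therapy referrals on record",
             "Any psychological-therapy referral",
             "Repeated psychological-therapy referrals"))
  for (rt in c("REF_CMHT", "REF_COUNS")) {
    col <- paste0("any_", tolower(sub("REF_", "", rt)), "_referral")
    ids <- unique(refs[type == rt, patient_id])
    feats[, (col) := as.integer(patient_id %in% ids)]
    add_meta(col, "binary", "Treatment", "fs_clinician",
             paste("Any referral of type", rt))
  }

  ## Inconsistency: temporal entropy of attendance ------------------------
  series <- build_attendance_series(cohort, n_years = params$attendance_years,
                                    index_date = index, patient_ids = pids)
  att <- .attendance_features(series, params)
  bind(att)
  add_meta(c("median_annual_dna", "sample_entropy_appointments",
             "spectral_entropy_nonattendance",
             "avg_quarterly_entropy_nonattendance",
             "active_information_nonattendance"),
           c("count", "continuous", "continuous", "continuous", "continuous"),
           "Inconsistency", "fs_interviews",
           c("Median annual count of non-attended appointments",
             "Sample entropy of monthly appointment counts",
             "Spectral entropy of monthly non-attendance",
             "Average entropy of quarterly non-attendance",
             "Active information of monthly non-attendance"))

  ## PatternsOfPrescription ----------------------------------------------
  feats[, n_aborted_antidepressant_regimes :=
          count_aborted_regimes(rx, med_class = "antidepressant",
                                gap_days = params$regime_gap_days,
                                min_duration_days = params$regime_min_duration_days,
                                index_date = index, patient_ids = pids)]
  add_meta("n_aborted_antidepressant_regimes", "count",
           "PatternsOfPrescription", "fs_literature",
           "Count of aborted antidepressant regimes")

  meds <- medications_of_interest()
  med_match <- .match_medication_name(rx$name, meds$name)
  rxm <- copy(rx)[, med := med_match][!is.na(med)]
  rxm <- merge(rxm, meds, by.x = "med", by.y = "name")[
    , .(patient_id, med, med_class = class.y, date)]
  win_start <- index - round(params$medication_window_years * 365.25)
  rxw <- rxm[date > win_start]
  nad <- rxw[med_class == "antidepressant", .N, by = patient_id]
  feats[, n_antidepressant_prescriptions := .fill0(nad, pids, "N")]
  add_meta("n_antidepressant_prescriptions", "count",
           "PatternsOfPrescription", "fs_clinician",
           "Antidepressant prescriptions in the lookback window")
  ndist <- rxw[, .(n = length(unique(med))), by = patient_id]
  feats[, n_distinct_medications_of_interest := .fill0(ndist, pids)]
  add_meta("n_distinct_medications_of_interest", "count",
           "PatternsOfPrescription", "fs_clinician",
           "Distinct medications of interest in the lookback window")

  ## RelevantPrescriptions / AntipsychoticPrescription --------------------
  nonap <- meds[class != "antipsychotic", name]
  for (m in nonap) {
    col <- paste0("med_", tolower(m))
    ids <- unique(rxw[med == m, patient_id])
    feats[, (col) := as.integer(patient_id %in% ids)]
  }
  add_meta(paste0("med_", tolower(nonap)), "binary", "RelevantPrescriptions",
           "fs_clinician", paste("Any prescription for", nonap))
  ad_ids <- unique(rxw[med_class == "antidepressant", patient_id])
  hyp_ids <- unique(rxw[med_class == "hypnotic_anxiolytic", patient_id])
  feats[, any_antidepressant := as.integer(patient_id %in% ad_ids)]
  feats[, any_hypnotic_anxiolytic := as.integer(patient_id %in% hyp_ids)]
  add_meta(c("any_antidepressant", "any_hypnotic_anxiolytic"), "binary",
           "RelevantPrescriptions", "fs_clinician",
           c("Any antidepressant of interest",
             "Any hypnotic/anxiolytic of interest"))
  ap_ids <- unique(rxw[med_class == "antipsychotic", patient_id])
  feats[, any_antipsychotic := as.integer(patient_id %in% ap_ids)]
  add_meta("any_antipsychotic", "binary", "AntipsychoticPrescription",
           "fs_clinician", "Any antipsychotic prescription")

  meta <- rbindlist(meta)
  stopifnot(!anyDuplicated(meta$feature_id),
            all(meta$feature_id %in% names(feats)))
  list(features = feats, meta = meta)
}

# left-join count helper: 0 for patients without rows
.fill0 <- function(agg, pids, col = "n") {
  out <- agg[data.table(patient_id = pids), on = "patient_id"]
  v <- out[[col]]
  fifelse(is.na(v), 0L, as.integer(v))
}
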