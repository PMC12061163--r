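#' Configuration for the synthetic cohort generator
#'
#' Parameters of the generative model used to emulate a primary-care
#' population in which complex mental health difficulties are present at a
#' realistic latent prevalence but heavily under-coded, so that observed
#' (records-based) caseness lands near 0.3% of the total population while the
#' latent prevalence is 3--5%.
#'
#' The generative model, per patient:
#' \itemize{
#'   \item latent complexity status ~ Bernoulli(`true_prevalence`);
#'   \item age at the index date uniform over `age_range` (stored as a birth
#'     year, mid-year birthday convention); registration duration uniform
#'     over `registration_years_range` (in years);
#'   \item an inclusion-list diagnosis is coded with probability
#'     `coding_probability` for latent cases (the under-coding dial) and
#'     `background_inclusion_probability` for non-cases;
#'   \item an exclusion diagnosis with probability `exclusion_probability`,
#'     independent of latent status;
#'   \item the number of distinct generic psychiatric codes is negative
#'     binomial with mean `diagnosis_mean` (dispersion size
#'     `diagnosis_dispersion`), multiplied by `diagnosis_rate_ratio` for
#'     latent cases -- the planted dose-dependent association. Patients
#'     whose inclusion diagnosis is actually coded have the mean further
#'     multiplied by `diagnosis_coded_boost` and may receive a second
#'     distinct inclusion code (probability
#'     `inclusion_second_code_probability`): recognition and richness of
#'     psychiatric coding travel together, so the observed (coded) cases
#'     show the monotone dose dependence on the diagnosis count that the
#'     screen is designed to recover;
#'   \item a medication of interest is prescribed within the lookback window
#'     with probability `medication_probability_case` /
#'     `medication_probability_control`; given any such medication, class
#'     membership is sampled with the antipsychotic probability inflated for
#'     latent cases on the odds scale by `antipsychotic_odds_multiplier`;
#'   \item appointments follow a Poisson process at `appointment_rate` per
#'     month over the registration period; each appointment is missed (DNA)
#'     with a logistic probability whose intercept is
#'     `qlogis(dna_probability)`, shifted by `log(dna_odds_multiplier)` for
#'     latent cases, plus Gaussian noise with standard deviation
#'     `dna_irregularity_sd` multiplied by `dna_irregularity_multiplier` for
#'     latent cases (cases miss appointments more, and more erratically);
#'   \item antecedent (childhood-adversity), concurrent
#'     (concerning-behaviour) codes and psychological-therapy referrals are
#'     Poisson with rates multiplied by `event_rate_ratio` for latent cases.
#' }
#'
#' All distributions are synthetic stand-ins chosen for plausibility; none
#' are estimates from real data.
#'
#' @param n_patients number of patients to simulate.
#' @param true_prevalence latent complexity prevalence.
#' @param coding_probability probability that a latent case has a coded
#'   inclusion diagnosis (under-coding: 0.10 emulates ten-fold
#'   under-diagnosis).
#' @param index_date study index date.
#' @param observation_years maximum registration duration, years (>= 2).
#' @param age_range integer age bounds at index for the simulated
#'   population (wider than the study-eligible 18--70 so the age filter is
#'   exercised).
#' @param registration_years_range range of the uniform registration
#'   duration, years.
#' @param background_inclusion_probability probability a non-case carries an
#'   inclusion diagnosis code.
#' @param exclusion_probability probability of an exclusion diagnosis.
#' @param medication_probability_case,medication_probability_control
#'   probability of at least one medication of interest within the
#'   medication lookback window.
#' @param medication_window_years lookback window used when dating
#'   medication-of-interest prescriptions.
#' @param diagnosis_mean,diagnosis_dispersion negative-binomial mean and
#'   size for the count of distinct generic psychiatric codes in non-cases.
#' @param diagnosis_rate_ratio multiplier on `diagnosis_mean` for latent
#'   cases.
#' @param diagnosis_coded_boost additional multiplier on the generic
#'   psychiatric code mean for patients with a coded inclusion diagnosis
#'   (coding-propensity coupling).
#' @param inclusion_second_code_probability probability that a coded
#'   patient carries a second distinct inclusion code.
#' @param antipsychotic_probability probability an antipsychotic is among a
#'   non-case's medications of interest, given any.
#' @param antipsychotic_odds_multiplier odds multiplier on the above for
#'   latent cases.
#' @param antidepressant_probability,hypnotic_probability class-membership
#'   probabilities given any medication of interest (at least one class is
#'   always present; antidepressant is the fallback).
#' @param prescriptions_per_medication mean number of issues per prescribed
#'   medication (1 + Poisson(mean - 1)).
#' @param appointment_rate appointments per month.
#' @param dna_probability baseline per-appointment non-attendance
#'   probability.
#' @param dna_odds_multiplier odds multiplier on non-attendance for latent
#'   cases.
#' @param dna_irregularity_sd standard deviation of the per-appointment
#'   logit noise for non-cases.
#' @param dna_irregularity_multiplier multiplier on that standard deviation
#'   for latent cases.
#' @param antecedent_rate,concurrent_rate,iapt_rate,other_referral_rate,
#'   other_code_rate Poisson rates for the remaining event types.
#' @param event_rate_ratio multiplier on antecedent/concurrent/IAPT rates
#'   for latent cases.
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 50000L,
                          true_prevalence = 0.04,
                          coding_probability = 0.10,
                          index_date = as.Date("2021-12-31"),
                          observation_years = 12L,
                          age_range = c(15L, 74L),
                          registration_years_range = c(0, observation_years),
                          background_inclusion_probability = 0.002,
                          exclusion_probability = 0.015,
                          medication_probability_case = 0.95,
                          medication_probability_control = 0.10,
                          medication_window_years = 10,
                          diagnosis_mean = 0.10,
                          diagnosis_dispersion = 0.8,
                          diagnosis_rate_ratio = 4,
                          diagnosis_coded_boost = 2.5,
                          inclusion_second_code_probability = 0.4,
                          antipsychotic_probability = 0.06,
                          antipsychotic_odds_multiplier = 5,
                          antidepressant_probability = 0.85,
                          hypnotic_probability = 0.30,
                          prescriptions_per_medication = 6,
                          appointment_rate = 0.35,
                          dna_probability = 0.08,
                          dna_odds_multiplier = 3,
                          dna_irregularity_sd = 0.5,
                          dna_irregularity_multiplier = 3,
                          antecedent_rate = 0.06,
                          concurrent_rate = 0.08,
                          iapt_rate = 0.05,
                          other_referral_rate = 0.04,
                          other_code_rate = 0.30,
                          event_rate_ratio = 3,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    true_prevalence = true_prevalence,
    coding_probability = coding_probability,
    index_date = as.Date(index_date),
    observation_years = as.integer(observation_years),
    age_range = as.integer(age_range),
    registration_years_range = as.numeric(registration_years_range),
    background_inclusion_probability = background_inclusion_probability,
    exclusion_probability = exclusion_probability,
    medication_probability_case = medication_probability_case,
    medication_probability_control = medication_probability_control,
    medication_window_years = medication_window_years,
    diagnosis_mean = diagnosis_mean,
    diagnosis_dispersion = diagnosis_dispersion,
    diagnosis_rate_ratio = diagnosis_rate_ratio,
    diagnosis_coded_boost = diagnosis_coded_boost,
    inclusion_second_code_probability = inclusion_second_code_probability,
    antipsychotic_probability = antipsychotic_probability,
    antipsychotic_odds_multiplier = antipsychotic_odds_multiplier,
    antidepressant_probability = antidepressant_probability,
    hypnotic_probability = hypnotic_probability,
    prescriptions_per_medication = prescriptions_per_medication,
    appointment_rate = appointment_rate,
    dna_probability = dna_probability,
    dna_odds_multiplier = dna_odds_multiplier,
    dna_irregularity_sd = dna_irregularity_sd,
    dna_irregularity_multiplier = dna_irregularity_multiplier,
    antecedent_rate = antecedent_rate,
    concurrent_rate = concurrent_rate,
    iapt_rate = iapt_rate,
    other_referral_rate = other_referral_rate,
    other_code_rate = other_code_rate,
    event_rate_ratio = event_rate_ratio,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  probs <- c("true_prevalence", "coding_probability",
             "background_inclusion_probability", "exclusion_probability",
             "medication_probability_case", "medication_probability_control",
             "antipsychotic_probability", "antidepressant_probability",
             "hypnotic_probability", "dna_probability",
             "inclusion_second_code_probability")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("configuration error: `", p, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  pos <- c("diagnosis_mean", "diagnosis_dispersion", "diagnosis_rate_ratio",
           "diagnosis_coded_boost",
           "antipsychotic_odds_multiplier", "prescriptions_per_medication",
           "appointment_rate", "dna_odds_multiplier", "dna_irregularity_sd",
           "dna_irregularity_multiplier", "antecedent_rate",
           "concurrent_rate", "iapt_rate", "other_referral_rate",
           "other_code_rate", "event_rate_ratio", "medication_window_years")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("configuration error: `", p, "` must be a finite non-negative number",
           call. = FALSE)
    }
  }
  if (cfg$n_patients < 1L) {
    stop("configuration error: n_patients must be >= 1", call. = FALSE)
  }
  if (cfg$observation_years < 2L) {
    stop("configuration error: observation_years must be >= 2", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2]) {
    stop("configuration error: age_range must be an increasing pair",
         call. = FALSE)
  }
  rr <- cfg$registration_years_range
  if (length(rr) != 2L || any(!is.finite(rr)) || rr[1] < 0 ||
      rr[1] > rr[2] || rr[2] > cfg$observation_years) {
    stop("configuration error: registration_years_range must lie within [0, observation_years]",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n_patients,
      "| latent prevalence =", x$true_prevalence,
      "| coding probability =", x$coding_probability,
      "| seed =", x$seed, "\n")
  invisible(x)
}

# uniform random dates in [from, to] (per-element vectors of Date)
.runif_date <- function(n, from, to) {
  span <- as.numeric(to - from)
  from + floor(runif(n) * (span + 1))
}

#' Generate a synthetic patient cohort
#'
#' Simulates patient event streams (demographics, dated diagnoses,
#' prescriptions, appointments with attended/DNA status, referrals) under
#' the generative model described in [cohort_config()]. The latent
#' complexity status is returned in a separate `truth` table and never
#' appears in the analysis-facing tables, mimicking a blinded analysis.
#'
#' @param config a [cohort_config()].
#' @param vocab a [code_vocabulary()]; defaults to [default_vocabulary()].
#' @return An object of class `mh_cohort`: a list with data.tables
#'   `patients` (patient_id, birth_year, registration_date), `diagnoses`
#'   (patient_id, code, date), `prescriptions` (patient_id, name, class,
#'   date), `appointments` (patient_id, date, status), `referrals`
#'   (patient_id, type, date), `truth` (patient_id, latent_status), plus the
#'   `config` used.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 500, seed = 42))
#' cohort
#' @export
generate_cohort <- function(config = cohort_config(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(vocab, "code_vocabulary"))
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  index <- config$index_date
  index_year <- as.integer(format(index, "%Y"))

  pid <- sprintf("P%07d", seq_len(n))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  birth_year <- index_year - age
  reg_years <- runif(n, config$registration_years_range[1],
                     config$registration_years_range[2])
  reg_date <- index - round(reg_years * 365.25)
  latent <- runif(n) < config$true_prevalence

  patients <- data.table(patient_id = pid, birth_year = birth_year,
                         registration_date = reg_date)
  truth <- data.table(patient_id = pid, latent_status = latent)

  pools <- split(vocab$codes$code, vocab$codes$role)
  inc_pool <- pools$inclusion
  exc_pool <- pools$exclusion
  psy_pool <- setdiff(pools$psychiatric, "MD000")
  ant_pool <- setdiff(pools$antecedent, "ANT000")
  con_pool <- setdiff(pools$concurrent, "CON000")
  oth_pool <- pools$other

  ## --- diagnoses -----------------------------------------------------
  # inclusion diagnoses (under-coded in latent cases)
  p_inc <- fifelse(latent, config$coding_probability,
                   config$background_inclusion_probability)
  has_inc <- runif(n) < p_inc
  dx_inc <- if (any(has_inc)) {
    idx <- which(has_inc)
    n_inc <- 1L + (runif(length(idx)) < config$inclusion_second_code_probability)
    codes <- unlist(lapply(seq_along(idx),
                           function(j) sample(inc_pool, n_inc[j])),
                    use.names = FALSE)
    ridx <- rep(idx, n_inc)
    data.table(patient_id = pid[ridx], code = codes,
               date = .runif_date(length(ridx), reg_date[ridx], index))
  }
  # exclusion diagnoses
  has_exc <- runif(n) < config$exclusion_probability
  dx_exc <- if (any(has_exc)) {
    idx <- which(has_exc)
    data.table(patient_id = pid[idx],
               code = sample(exc_pool, length(idx), replace = TRUE),
               date = .runif_date(length(idx), reg_date[idx], index))
  }
  # distinct generic psychiatric codes: planted dose-dependent count
  mu <- config$diagnosis_mean *
    fifelse(latent, config$diagnosis_rate_ratio, 1) *
    fifelse(has_inc, config$diagnosis_coded_boost, 1)
  k_psy <- pmin(rnbinom(n, size = config$diagnosis_dispersion, mu = mu),
                length(psy_pool))
  dx_psy <- .sample_distinct_codes(pid, k_psy, psy_pool, reg_date, index,
                                   duplicate_mean = 0.4)
  # antecedent / concurrent / other codes
  mult <- fifelse(latent, config$event_rate_ratio, 1)
  k_ant <- pmin(rpois(n, config$antecedent_rate * mult), length(ant_pool))
  dx_ant <- .sample_distinct_codes(pid, k_ant, ant_pool, reg_date, index)
  k_con <- pmin(rpois(n, config$concurrent_rate * mult), length(con_pool))
  dx_con <- .sample_distinct_codes(pid, k_con, con_pool, reg_date, index)
  k_oth <- pmin(rpois(n, config$other_code_rate), length(oth_pool))
  dx_oth <- .sample_distinct_codes(pid, k_oth, oth_pool, reg_date, index)

  diagnoses <- rbindlist(
    Filter(Negate(is.null), list(dx_inc, dx_exc, dx_psy, dx_ant, dx_con, dx_oth)))
  if (!nrow(diagnoses)) {
    diagnoses <- data.table(patient_id = character(), code = character(),
                            date = as.Date(character()))
  }

  ## --- prescriptions -------------------------------------------------
  meds <- medications_of_interest()
  p_med <- fifelse(latent, config$medication_probability_case,
                   config$medication_probability_control)
  has_med <- runif(n) < p_med
  p_ap_case <- plogis(qlogis(config$antipsychotic_probability) +
                        log(config$antipsychotic_odds_multiplier))
  p_ap <- fifelse(latent, p_ap_case, config$antipsychotic_probability)
  cls_ad <- has_med & runif(n) < config$antidepressant_probability
  cls_hyp <- has_med & runif(n) < config$hypnotic_probability
  cls_ap <- has_med & runif(n) < p_ap
  none <- has_med & !(cls_ad | cls_hyp | cls_ap)
  cls_ad <- cls_ad | none  # at least one class when any medication

  med_start <- pmax(reg_date,
                    index - round(config$medication_window_years * 365.25) + 1)
  rx <- rbindlist(list(
    .sample_prescriptions(pid, cls_ad, meds[class == "antidepressant"],
                          med_start, index, config),
    .sample_prescriptions(pid, cls_ap, meds[class == "antipsychotic"],
                          med_start, index, config),
    .sample_prescriptions(pid, cls_hyp, meds[class == "hypnotic_anxiolytic"],
                          med_start, index, config)
  ))
  # non-interest prescriptions, dated anywhere in the record
  other_meds <- c("Amoxicillin", "Atorvastatin", "Omeprazole", "Salbutamol",
                  "Paracetamol", "Ibuprofen")
  has_oth_med <- runif(n) < 0.30
  rx_oth <- if (any(has_oth_med)) {
    idx <- which(has_oth_med)
    nper <- 1L + rpois(length(idx), 1)
    ridx <- rep(idx, nper)
    data.table(patient_id = pid[ridx],
               name = sample(other_meds, length(ridx), replace = TRUE),
               class = "other",
               date = .runif_date(length(ridx), reg_date[ridx], index))
  }
  prescriptions <- rbindlist(Filter(Negate(is.null), list(rx, rx_oth)))
  if (!nrow(prescriptions)) {
    prescriptions <- data.table(patient_id = character(), name = character(),
                                class = character(), date = as.Date(character()))
  }

  ## --- appointments --------------------------------------------------
  dur_days <- as.numeric(index - reg_date)
  n_appt <- rpois(n, config$appointment_rate * dur_days / 30.4375)
  aidx <- rep(seq_len(n), n_appt)
  if (length(aidx)) {
    adate <- .runif_date(length(aidx), reg_date[aidx], index)
    logit_p <- qlogis(config$dna_probability) +
      fifelse(latent[aidx], log(config$dna_odds_multiplier), 0) +
      rnorm(length(aidx), 0, config$dna_irregularity_sd *
              fifelse(latent[aidx], config$dna_irregularity_multiplier, 1))
    dna <- runif(length(aidx)) < plogis(logit_p)
    appointments <- data.table(patient_id = pid[aidx], date = adate,
                               status = fifelse(dna, "DNA", "attended"))
  } else {
    appointments <- data.table(patient_id = character(),
                               date = as.Date(character()),
                               status = character())
  }

  ## --- referrals -----------------------------------------------------
  k_iapt <- rpois(n, config$iapt_rate * mult)
  k_cmht <- rpois(n, config$other_referral_rate / 2)
  k_couns <- rpois(n, config$other_referral_rate / 2)
  ref <- rbindlist(list(
    .expand_referrals(pid, k_iapt, "REF_IAPT", reg_date, index),
    .expand_referrals(pid, k_cmht, "REF_CMHT", reg_date, index),
    .expand_referrals(pid, k_couns, "REF_COUNS", reg_date, index)
  ))
  referrals <- if (nrow(ref)) ref else
    data.table(patient_id = character(), type = character(),
               date = as.Date(character()))

  setorder(diagnoses, patient_id, date, code)
  setorder(prescriptions, patient_id, date, name)
  setorder(appointments, patient_id, date, status)
  setorder(referrals, patient_id, date, type)

  structure(list(patients = patients, diagnoses = diagnoses,
                 prescriptions = prescriptions, appointments = appointments,
                 referrals = referrals, truth = truth, config = config),
            class = "mh_cohort")
}

# draw k_i distinct codes per patient from a pool, with optional duplicate
# events per selected code
.sample_distinct_codes <- function(pid, k, pool, reg_date, index,
                                   duplicate_mean = 0) {
  idx <- which(k > 0)
  if (!length(idx)) return(NULL)
  codes <- unlist(lapply(idx, function(i) sample(pool, k[i])),
                  use.names = FALSE)
  ridx <- rep(idx, k[idx])
  out <- data.table(patient_id = pid[ridx], code = codes, ridx = ridx)
  if (duplicate_mean > 0) {
    nev <- 1L + rpois(nrow(out), duplicate_mean)
    out <- out[rep(seq_len(.N), nev)]
  }
  out[, date := .runif_date(.N, reg_date[ridx], index)]
  out[, ridx := NULL]
  out
}

.sample_prescriptions <- function(pid, flag, med_tab, win_start, index, config) {
  idx <- which(flag)
  if (!length(idx)) return(NULL)
  # one or (with probability 0.3) two distinct products of the class
  n_names <- 1L + (runif(length(idx)) < 0.3)
  n_names <- pmin(n_names, nrow(med_tab))
  ridx <- rep(idx, n_names)
  nm <- unlist(lapply(seq_along(idx), function(j)
    sample(med_tab$name, n_names[j])), use.names = FALSE)
  n_rx <- 1L + rpois(length(ridx), max(config$prescriptions_per_medication - 1, 0))
  eidx <- rep(seq_along(ridx), n_rx)
  data.table(patient_id = pid[ridx][eidx],
             name = nm[eidx],
             class = med_tab$class[1],
             date = .runif_date(length(eidx), win_start[ridx][eidx], index))
}

.expand_referrals <- function(pid, k, type, reg_date, index) {
  idx <- which(k > 0)
  if (!length(idx)) return(NULL)
  ridx <- rep(idx, k[idx])
  data.table(patient_id = pid[ridx], type = type,
             date = .runif_date(length(ridx), reg_date[ridx], index))
}

#' @export
print.mh_cohort <- function(x, ...) {
  cat("<mh_cohort> ", nrow(x$patients), " patients | ",
      nrow(x$diagnoses), " diagnoses | ",
      nrow(x$prescriptions), " prescriptions | ",
      nrow(x$appointments), " appointments | ",
      nrow(x$referrals), " referrals\n", sep = "")
  invisible(x)
}

#' Write / read a cohort as delimited text files
#'
#' One CSV per event type plus a patients file. The latent truth is written
#' to its own file (`truth.csv`) and is never part of the analysis-facing
#' tables; `read_cohort()` only loads it on request.
#'
#' @param cohort an `mh_cohort`.
#' @param dir output directory (created if needed).
#' @param include_truth write `truth.csv` alongside the analysis tables?
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   an `mh_cohort` (with a `truth` element only when `with_truth = TRUE`).
#' @export
write_cohort <- function(cohort, dir, include_truth = TRUE) {
  stopifnot(inherits(cohort, "mh_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(cohort$patients, file.path(dir, "patients.csv"))
  fwrite(cohort$diagnoses, file.path(dir, "diagnoses.csv"))
  fwrite(cohort$prescriptions, file.path(dir, "prescriptions.csv"))
  fwrite(cohort$appointments, file.path(dir, "appointments.csv"))
  fwrite(cohort$referrals, file.path(dir, "referrals.csv"))
  if (include_truth) fwrite(cohort$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(
    c(list(index_date = as.character(cohort$config$index_date)),
      cohort$config[setdiff(names(cohort$config), "index_date")]),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param with_truth also load `truth.csv`?
#' @export
read_cohort <- function(dir, with_truth = FALSE) {
  rd <- function(f, datecols = "date") {
    dt <- fread(file.path(dir, f))
    for (dc in intersect(datecols, names(dt))) {
      dt[, (dc) := as.Date(get(dc))]
    }
    dt
  }
  out <- list(
    patients = rd("patients.csv", "registration_date"),
    diagnoses = rd("diagnoses.csv"),
    prescriptions = rd("prescriptions.csv"),
    appointments = rd("appointments.csv"),
    referrals = rd("referrals.csv"),
    truth = NULL, config = NULL
  )
  if (with_truth && file.exists(file.path(dir, "truth.csv"))) {
    out$truth <- fread(file.path(dir, "truth.csv"))
  }
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    out$config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }
  structure(out, class = "mh_cohort")
}
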