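#' Phenotype specification for the study population and caseness
#'
#' Encodes the records-based definition of the study population and of
#' caseness for complex mental health difficulties:
#' \itemize{
#'   \item study population: aged 18--70 inclusive at the index date,
#'     registered with their practice for at least one year at the index
#'     date, with either a mental-disorder code or a medication of interest
#'     within the lookback window, and no exclusion diagnosis ever;
#'   \item caseness: at least one inclusion-list diagnosis at any time up to
#'     the index date AND a medication of interest within the lookback
#'     window (and membership of the study population).
#' }
#'
#' Date windows are half-open `(index - lookback, index]`: an event exactly
#' `lookback_years` before the index date is outside the window. Age is
#' computed as completed years at the index date from the birth year with a
#' mid-year (1 July) birthday convention, since the anonymised records store
#' the birth year only.
#'
#' @param index_date index date.
#' @param lookback_years lookback for the medication and recent-diagnosis
#'   windows.
#' @param age_min,age_max inclusive age bounds.
#' @param min_registration_years minimum registration duration at index.
#' @param inclusion_roots,exclusion_roots root codes of the inclusion and
#'   exclusion diagnosis lists; all descendants are searched too.
#' @param mental_disorder_root root code whose descendant closure defines
#'   "a mental-disorder code" for study-population entry.
#' @param medications data.frame of medications of interest (columns `name`,
#'   `class`); matching is case-insensitive substring on the product name.
#' @return A list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(index_date = as.Date("2021-12-31"),
                           lookback_years = 10,
                           age_min = 18L, age_max = 70L,
                           min_registration_years = 1,
                           inclusion_roots = c("INC_PD", "INC_DYS", "INC_PDD",
                                               "INC_CHRDEP", "INC_CPTSD",
                                               "INC_CHRPTSD"),
                           exclusion_roots = c("EXC_BIP", "EXC_SCZ", "EXC_DEM"),
                           mental_disorder_root = "MD000",
                           medications = medications_of_interest()) {
  if (age_min > age_max) stop("age_min must be <= age_max", call. = FALSE)
  if (lookback_years <= 0) stop("lookback_years must be > 0", call. = FALSE)
  structure(list(
    index_date = as.Date(index_date),
    lookback_years = lookback_years,
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    min_registration_years = min_registration_years,
    inclusion_roots = inclusion_roots,
    exclusion_roots = exclusion_roots,
    mental_disorder_root = mental_disorder_root,
    medications = as.data.table(medications)
  ), class = "phenotype_spec")
}

# completed years at index, mid-year birthday convention; NA-safe
.age_at_index <- function(birth_year, index_date) {
  out <- rep(NA_real_, length(birth_year))
  ok <- !is.na(birth_year)
  if (any(ok)) {
    birthday <- as.Date(paste0(birth_year[ok], "-07-01"))
    out[ok] <- floor(as.numeric(index_date - birthday) / 365.25)
  }
  out
}

# case-insensitive substring match of prescription names against the
# medication-of-interest list; returns logical vector over `names`
.match_medications <- function(names, med_names) {
  lname <- tolower(names)
  hit <- rep(FALSE, length(lname))
  for (m in tolower(med_names)) {
    hit <- hit | grepl(m, lname, fixed = TRUE)
  }
  hit
}

#' Build the study population and assign caseness
#'
#' Applies the eligibility filters and the caseness algorithm to a cohort,
#' returning one label row per patient with the component criterion flags.
#' Patients with a missing birth year or registration date are excluded
#' from the study population; their number is reported as a warning count
#' in the `n_missing_demographics` attribute.
#'
#' @param cohort an `mh_cohort` (or any list with the same tables).
#' @param spec a [phenotype_spec()].
#' @param vocab the [code_vocabulary()] used to expand diagnosis code roots.
#' @return data.table with columns `patient_id`, `eligible_age`,
#'   `eligible_registration`, `has_recent_mental_code`,
#'   `has_inclusion_diagnosis`, `has_recent_medication`,
#'   `has_exclusion_diagnosis`, `in_study_population`, `is_case`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 7))
#' labels <- build_study_population(cohort, phenotype_spec())
#' table(labels$in_study_population, labels$is_case)
#' @export
build_study_population <- function(cohort, spec = phenotype_spec(),
                                   vocab = default_vocabulary()) {
  stopifnot(inherits(spec, "phenotype_spec"))
  patients <- as.data.table(cohort$patients)
  dx <- as.data.table(cohort$diagnoses)
  rx <- as.data.table(cohort$prescriptions)
  index <- spec$index_date
  window_start <- index - round(spec$lookback_years * 365.25)  # exclusive
  min_reg_days <- round(spec$min_registration_years * 365.25) - 0.5

  missing_demo <- is.na(patients$birth_year) |
    is.na(patients$registration_date)
  n_missing <- sum(missing_demo)
  if (n_missing > 0) {
    warning(n_missing,
            " patient(s) with missing demographics excluded from the study population")
  }

  inc_codes <- code_closure(vocab, spec$inclusion_roots)
  exc_codes <- code_closure(vocab, spec$exclusion_roots)
  md_codes <- code_closure(vocab, spec$mental_disorder_root)

  age <- .age_at_index(patients$birth_year, index)
  eligible_age <- !missing_demo & age >= spec$age_min & age <= spec$age_max
  reg_days <- as.numeric(index - patients$registration_date)
  eligible_reg <- !missing_demo & reg_days >= min_reg_days

  has_flag <- function(ids) patients$patient_id %in% unique(ids)
  dx_valid <- dx[!is.na(date) & date <= index]
  has_inc <- has_flag(dx_valid[code %in% inc_codes, patient_id])
  has_exc <- has_flag(dx_valid[code %in% exc_codes, patient_id])
  has_md_recent <- has_flag(
    dx_valid[code %in% md_codes & date > window_start, patient_id])

  rx_valid <- rx[!is.na(date) & date > window_start & date <= index]
  med_hit <- .match_medications(rx_valid$name, spec$medications$name)
  has_med <- has_flag(rx_valid[med_hit, patient_id])

  in_pop <- eligible_age & eligible_reg & (has_md_recent | has_med) & !has_exc
  is_case <- in_pop & has_inc & has_med & !has_exc

  out <- data.table(
    patient_id = patients$patient_id,
    eligible_age = eligible_age,
    eligible_registration = eligible_reg,
    has_recent_mental_code = has_md_recent,
    has_inclusion_diagnosis = has_inc,
    has_recent_medication = has_med,
    has_exclusion_diagnosis = has_exc,
    in_study_population = in_pop,
    is_case = is_case
  )
  setattr(out, "n_missing_demographics", n_missing)
  setattr(out, "index_date", index)
  out[]
}

#' Caseness summary from population counts
#'
#' Reproduces the headline cohort arithmetic: the study-population share of
#' the total population and the caseness share of the study population and
#' of the total population, as percentages (one decimal place, matching the
#' reporting convention for these shares).
#'
#' @param n_total,n_study,n_cases patient counts (already
#'   disclosure-controlled if they are to be published).
#' @return data.table with columns `quantity`, `count`, `percent`.
#' @examples
#' caseness_summary(1155340, 155470, 3040)
#' @export
caseness_summary <- function(n_total, n_study, n_cases) {
  stopifnot(n_total >= n_study, n_study >= n_cases)
  data.table(
    quantity = c("total_population", "study_population",
                 "cases", "cases_of_study_population"),
    count = c(n_total, n_study, n_cases, n_cases),
    percent = round(100 * c(n_total / n_total, n_study / n_total,
                            n_cases / n_total, n_cases / n_study), 1)
  )
}

#' Summarise caseness criteria over a labelled cohort
#'
#' Produces the study-population breakdown: counts and percentages for the
#' total population, the study population, each caseness criterion within
#' the study population, and caseness itself. Counts are
#' disclosure-controlled (suppressed if <= 7, else rounded to the nearest
#' ten) before any percentage is computed, so published figures never expose
#' a small raw count.
#'
#' @param labels output of [build_study_population()].
#' @param disclosure apply disclosure control to counts before computing
#'   percentages?
#' @return data.table with columns `quantity`, `count`, `denominator`,
#'   `percent`. Suppressed counts appear as `NA`.
#' @export
summarize_caseness <- function(labels, disclosure = TRUE) {
  labels <- as.data.table(labels)
  ctrl <- if (disclosure) disclosure_control else identity
  n_total <- ctrl(nrow(labels))
  sp <- labels[in_study_population == TRUE]
  n_study <- ctrl(nrow(sp))
  counts <- c(
    study_population = nrow(sp),
    inclusion_diagnosis = sp[has_inclusion_diagnosis == TRUE, .N],
    recent_medication = sp[has_recent_medication == TRUE, .N],
    caseness = sp[is_case == TRUE, .N]
  )
  counts <- ctrl(counts)
  out <- data.table(
    quantity = c("total_population", "study_population",
                 "inclusion_diagnosis", "recent_medication",
                 "caseness", "caseness_of_total"),
    count = c(n_total, counts[["study_population"]],
              counts[["inclusion_diagnosis"]], counts[["recent_medication"]],
              counts[["caseness"]], counts[["caseness"]]),
    denominator = c(n_total, n_total, counts[["study_population"]],
                    counts[["study_population"]], counts[["study_population"]],
                    n_total)
  )
  out[, percent := round(100 * count / denominator, 1)]
  out[]
}
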