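#' Configuration for a full screening run
#'
#' Bundles the per-stage settings: cohort generation (or a directory of
#' existing event tables), phenotype specification, feature-extraction
#' parameters, the combination census, and the mutual-information estimator
#' settings. One master seed fans out to fixed per-stage sub-seeds so every
#' stage is individually reproducible.
#'
#' @param seed master seed for the run.
#' @param out_dir optional output directory for the run artifacts.
#' @param cohort_dir optional directory of event tables written by
#'   [write_cohort()]; when `NULL` a cohort is simulated.
#' @param cohort named list of overrides for [cohort_config()].
#' @param phenotype named list of overrides for [phenotype_spec()].
#' @param features named list of overrides for [feature_params()].
#' @param mi list with `k` and `n_runs` for [knn_mixed_mi()].
#' @param combinations list with `prune`, `cap`, `scan_limit` for
#'   [enumerate_combinations()].
#' @param top_n feature sets per type in the headline report.
#' @param or_correction continuity correction for odds ratios?
#' @param disclosure apply disclosure control to the published summary?
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, cohort_dir = NULL,
                       cohort = list(), phenotype = list(),
                       features = list(),
                       mi = list(k = 3L, n_runs = 20L),
                       combinations = list(prune = TRUE, cap = 1000L,
                                           scan_limit = 50000L),
                       top_n = 5L, or_correction = FALSE,
                       disclosure = TRUE) {
  mi <- modifyList(list(k = 3L, n_runs = 20L), mi)
  combinations <- modifyList(list(prune = TRUE, cap = 1000L,
                                  scan_limit = 50000L), combinations)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort_dir = cohort_dir, cohort = cohort,
                 phenotype = phenotype, features = features, mi = mi,
                 combinations = combinations, top_n = top_n,
                 or_correction = or_correction, disclosure = disclosure),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file may contain any of the fields of [run_config()]; nested
#' sections (`cohort`, `phenotype`, `features`, `mi`, `combinations`) are
#' passed through as overrides.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, cfg)
}

.mode_value <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  tab <- sort(table(v), decreasing = TRUE)
  as.numeric(names(tab)[1])
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate (or load) -> phenotype -> extract -> aggregate ->
#' rank -> evaluate as one reproducible run: generates or reads the cohort,
#' builds the study population and caseness labels, extracts component
#' features for the study population, assigns family levels and enumerates
#' feature-family combinations, ranks every informative feature set by
#' mutual information scaled to the caseness entropy, computes the
#' evaluation statistics for all binary feature sets (with disclosure
#' control), and assembles a run manifest with per-stage counts. When
#' `config$out_dir` is set, every artifact is (re)written from scratch as
#' delimited text plus a JSON manifest.
#'
#' @param config a [run_config()].
#' @param vocab a [code_vocabulary()].
#' @param cohort optionally, an existing `mh_cohort` (overrides simulation
#'   and `cohort_dir`).
#' @param quiet suppress progress messages?
#' @return list of class `mh_run` with elements `cohort`, `labels`,
#'   `caseness_summary`, `features`, `levels`, `combinations`, `ranked`,
#'   `evaluation`, `report`, `rank_plot`, `manifest`, `config`.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 5, cohort = list(n_patients = 2000),
#'                                combinations = list(cap = 200)))
#' head(run$ranked)
#' }
#' @export
run_pipeline <- function(config = run_config(), vocab = default_vocabulary(),
                         cohort = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[mhscreen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate ----------------------------------------------------------
  if (is.null(cohort)) {
    cohort <- stage("simulate", {
      if (!is.null(config$cohort_dir)) {
        say("reading cohort from ", config$cohort_dir)
        read_cohort(config$cohort_dir)
      } else {
        cc <- do.call(cohort_config,
                      modifyList(config$cohort, list(seed = config$seed)))
        say("simulating cohort: n = ", cc$n_patients)
        generate_cohort(cc, vocab)
      }
    })
  }

  ## phenotype ----------------------------------------------------------
  spec <- do.call(phenotype_spec, config$phenotype)
  labels <- stage("phenotype", build_study_population(cohort, spec, vocab))
  n_study <- labels[in_study_population == TRUE, .N]
  n_cases <- labels[is_case == TRUE, .N]
  say("study population ", n_study, " of ", nrow(labels),
      "; cases ", n_cases)
  case_summary <- summarize_caseness(labels, disclosure = config$disclosure)

  ## features -----------------------------------------------------------
  params <- do.call(feature_params, config$features)
  fm <- stage("extract",
              build_feature_matrix(cohort, labels, vocab, params,
                                   index_date = spec$index_date))
  say(nrow(fm$meta), " component features for ", nrow(fm$features),
      " patients")

  ## families + combinations --------------------------------------------
  lv <- stage("aggregate", assign_levels(fm))
  combos <- stage("aggregate",
                  enumerate_combinations(lv,
                                         prune = config$combinations$prune,
                                         cap = config$combinations$cap,
                                         scan_limit = config$combinations$scan_limit))
  say(ncol(combos$columns) - 1L, " combination feature sets emitted")

  ## rank ----------------------------------------------------------------
  sp_ids <- fm$features$patient_id
  stopifnot(identical(sp_ids, lv$indicators$patient_id),
            identical(sp_ids, combos$columns$patient_id))
  caseness <- labels[data.table(patient_id = sp_ids),
                     on = "patient_id", as.integer(is_case)]
  columns <- cbind(fm$features,
                   lv$indicators[, -"patient_id"],
                   combos$columns[, -"patient_id"])
  fam_ids <- setdiff(names(lv$indicators), "patient_id")
  combo_ids <- setdiff(names(combos$columns), "patient_id")
  meta_all <- rbindlist(list(
    fm$meta[, .(feature_id, value_type, set_type = "component")],
    data.table(feature_id = fam_ids, value_type = "binary",
               set_type = "family"),
    data.table(feature_id = combo_ids, value_type = "binary",
               set_type = "combination")
  ))
  ranked <- stage("rank",
                  rank_feature_sets(columns, meta_all, caseness,
                                    k = config$mi$k,
                                    n_runs = config$mi$n_runs,
                                    seed = config$seed + 500009L))
  say(nrow(ranked), " feature sets ranked (",
      attr(ranked, "n_non_informative"), " non-informative excluded)")

  ## evaluate -------------------------------------------------------------
  bin_ids <- meta_all[value_type == "binary", feature_id]
  bin_ids <- intersect(bin_ids, ranked$feature_id)
  evaluation <- stage("evaluate",
                      evaluate_feature_sets(columns, caseness,
                                            feature_ids = bin_ids,
                                            or_correction = config$or_correction))
  evaluation <- merge(evaluation,
                      ranked[, .(feature_id, set_type, mi_scaled_pct, rank)],
                      by = "feature_id")
  setorder(evaluation, rank)

  ## headline report (top feature sets per type) --------------------------
  report <- stage("report", {
    top <- ranked[, head(.SD, config$top_n), by = set_type]
    rows <- lapply(seq_len(nrow(top)), function(i) {
      fid <- top$feature_id[i]
      vt <- top$value_type[i]
      out <- data.table(feature_id = fid, set_type = top$set_type[i],
                        mi_scaled_pct = top$mi_scaled_pct[i],
                        rank = top$rank[i],
                        mean = NA_real_, mode = NA_real_,
                        prevalence_per_1000 = NA_real_, cba = NA_real_,
                        odds_ratio = NA_real_, ppv = NA_real_,
                        npv = NA_real_)
      if (vt == "binary") {
        ev <- evaluation[feature_id == fid]
        out[, `:=`(prevalence_per_1000 = ev$prevalence_per_1000,
                   cba = ev$cba, odds_ratio = ev$odds_ratio,
                   ppv = ev$ppv, npv = ev$npv)]
      } else if (vt == "count") {
        out[, mode := .mode_value(columns[[fid]])]
      } else {
        out[, mean := mean(columns[[fid]], na.rm = TRUE)]
      }
      out
    })
    rbindlist(rows)
  })

  rank_plot <- ranked[, .(feature_id, set_type, rank,
                          log10_rank = log10(rank), mi_scaled_pct)]

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mhscreen")),
    n_patients = nrow(labels),
    n_study_population = n_study,
    n_cases = n_cases,
    caseness_fraction_of_total = n_cases / nrow(labels),
    caseness_fraction_of_study = if (n_study > 0) n_cases / n_study else NA,
    caseness_entropy_nats = attr(ranked, "caseness_entropy_nats"),
    n_component_features = nrow(fm$meta),
    n_family_sets = length(fam_ids),
    n_combination_sets = length(combo_ids),
    n_feature_sets_ranked = nrow(ranked),
    n_non_informative = attr(ranked, "n_non_informative"),
    n_skipped_small_class = attr(ranked, "n_skipped"),
    n_suppressed_cells = sum(is.na(evaluation[, .(tp, fp, fn, tn)])),
    top_feature_id = ranked$feature_id[1],
    top_feature_mi_scaled_pct = ranked$mi_scaled_pct[1]
  )

  run <- structure(list(cohort = cohort, labels = labels,
                        caseness_summary = case_summary, features = fm,
                        levels = lv, combinations = combos, ranked = ranked,
                        evaluation = evaluation, report = report,
                        rank_plot = rank_plot, manifest = manifest,
                        config = config),
                   class = "mh_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.mh_run <- function(x, ...) {
  m <- x$manifest
  cat("<mh_run> seed ", m$seed, ": ", m$n_patients, " patients, ",
      m$n_study_population, " in study population, ", m$n_cases, " cases\n",
      "  caseness entropy ", signif(m$caseness_entropy_nats, 3), " nats; ",
      m$n_feature_sets_ranked, " feature sets ranked\n",
      "  top feature: ", m$top_feature_id, " (scaled MI ",
      signif(m$top_feature_mi_scaled_pct, 3), "%)\n", sep = "")
  invisible(x)
}

#' Write the artifacts of a pipeline run
#'
#' Writes every table as delimited text plus the JSON manifest. Files are
#' always regenerated from scratch.
#'
#' @param run an `mh_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(run$labels, file.path(dir, "labels.csv"))
  fwrite(run$caseness_summary, file.path(dir, "caseness_summary.csv"))
  fwrite(run$features$features, file.path(dir, "feature_matrix.csv"))
  fwrite(run$features$meta, file.path(dir, "feature_meta.csv"))
  fwrite(run$levels$assignments, file.path(dir, "family_assignments.csv"))
  fwrite(run$levels$cutpoints, file.path(dir, "family_cutpoints.csv"))
  fwrite(run$combinations$specs, file.path(dir, "combination_specs.csv"))
  fwrite(run$ranked, file.path(dir, "ranked_feature_sets.csv"))
  fwrite(run$evaluation, file.path(dir, "evaluation.csv"))
  fwrite(run$report, file.path(dir, "report.csv"))
  fwrite(run$rank_plot, file.path(dir, "rank_plot.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
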