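#' Canonical feature-family order and identifier letters
#' @keywords internal
family_order <- function() {
  c(Antecedent = "A", Concurrent = "C", ServiceUse = "S", Treatment = "T",
    Inconsistency = "I", PatternsOfPrescription = "P",
    RelevantPrescriptions = "R", AntipsychoticPrescription = "AP")
}

family_levels <- function() c("None", "NotNone", "Few", "Some", "Many")

.level_chars <- c(x = "x", None = "0", NotNone = "1", Few = "f",
                  Some = "s", Many = "m")

# is each component feature "present" in a patient's record?
# binary -> value 1; count -> > 0; continuous -> observed and > 0
.component_presence <- function(features, meta) {
  pres <- data.table(patient_id = features$patient_id)
  for (i in seq_len(nrow(meta))) {
    fid <- meta$feature_id[i]
    v <- features[[fid]]
    p <- switch(meta$value_type[i],
                binary = v == 1L,
                count = !is.na(v) & v > 0,
                continuous = !is.na(v) & v > 0)
    pres[, (fid) := as.integer(p)]
  }
  pres
}

#' Assign family count levels
#'
#' Aggregates the component features of each of the eight families into a
#' per-patient component count (how many of the family's features are
#' present in the record), then derives the five level indicators: `None`
#' (count 0), `NotNone` (count >= 1), and `Few`/`Some`/`Many` partitioning
#' the positive counts at family-specific quantile cutpoints. The default
#' cutpoints are the tertiles of the observed positive counts, computed once
#' over all patients before any level is assigned (a reproducible substitute
#' for subjectively chosen quantiles, overridable via `cutpoints`).
#'
#' @param feature_matrix output of [build_feature_matrix()] (list with
#'   `features` and `meta`).
#' @param cutpoints optional data.table (`family`, `q_low`, `q_high`)
#'   overriding the tertile defaults; `0 < q_low <= q_high`.
#' @return list of class `family_levels` with elements `assignments`
#'   (long data.table: `patient_id`, `family`, `component_count`, and
#'   logical `None`, `NotNone`, `Few`, `Some`, `Many`), `cutpoints`, and
#'   `indicators` (wide 0/1 data.table with one `family_<name>_<level>`
#'   column per family level).
#' @export
assign_levels <- function(feature_matrix, cutpoints = NULL) {
  features <- feature_matrix$features
  meta <- feature_matrix$meta
  fams <- names(family_order())
  empty <- setdiff(fams, unique(meta$family))
  if (length(empty)) {
    stop("configuration error: family with no member features: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  pres <- .component_presence(features, meta)
  counts <- data.table(patient_id = features$patient_id)
  for (fam in fams) {
    member <- meta[family == fam, feature_id]
    counts[, (fam) := rowSums(pres[, member, with = FALSE])]
  }
  if (is.null(cutpoints)) {
    cutpoints <- rbindlist(lapply(fams, function(fam) {
      pos <- counts[[fam]][counts[[fam]] > 0]
      if (!length(pos)) pos <- 1
      data.table(family = fam,
                 q_low = as.numeric(quantile(pos, 1 / 3, type = 1)),
                 q_high = as.numeric(quantile(pos, 2 / 3, type = 1)))
    }))
  } else {
    cutpoints <- as.data.table(cutpoints)
    stopifnot(all(fams %in% cutpoints$family),
              all(cutpoints$q_low > 0),
              all(cutpoints$q_low <= cutpoints$q_high))
  }
  assignments <- rbindlist(lapply(fams, function(fam) {
    cc <- counts[[fam]]
    qs <- cutpoints[family == fam]
    data.table(patient_id = counts$patient_id, family = fam,
               component_count = cc,
               None = cc == 0,
               NotNone = cc >= 1,
               Few = cc >= 1 & cc <= qs$q_low,
               Some = cc > qs$q_low & cc <= qs$q_high,
               Many = cc > qs$q_high)
  }))
  indicators <- data.table(patient_id = counts$patient_id)
  for (fam in fams) {
    a <- assignments[family == fam]
    for (lv in family_levels()) {
      indicators[, (paste0("family_", fam, "_", lv)) := as.integer(a[[lv]])]
    }
  }
  structure(list(assignments = assignments, cutpoints = cutpoints,
                 indicators = indicators),
            class = "family_levels")
}

#' Evaluate a feature-family combination
#'
#' A combination constrains some families to a level and leaves the rest
#' irrelevant (wildcard `"x"`). A patient's record satisfies the
#' combination iff every constrained family's level indicator is true; the
#' wildcard imposes no constraint. For example, Antecedent = "NotNone" with
#' Concurrent = "None" is true for a record with antecedent-family features
#' but no concurrent-family features, regardless of the other families.
#'
#' @param selectors named character vector over the eight families with
#'   values in `c("x", "None", "NotNone", "Few", "Some", "Many")`; at least
#'   one selector must differ from `"x"`.
#' @param levels a `family_levels` object from [assign_levels()].
#' @return integer 0/1 vector aligned with `levels$indicators$patient_id`.
#' @export
evaluate_combination <- function(selectors, levels) {
  fams <- names(family_order())
  stopifnot(all(names(selectors) %in% fams))
  sel <- selectors[selectors != "x"]
  if (!length(sel)) stop("all-wildcard combination is not allowed", call. = FALSE)
  ind <- levels$indicators
  out <- rep(TRUE, nrow(ind))
  for (fam in names(sel)) {
    out <- out & (ind[[paste0("family_", fam, "_", sel[[fam]])]] == 1L)
  }
  as.integer(out)
}

#' Combination identifier string
#' @keywords internal
combination_id <- function(selectors) {
  letters <- family_order()
  paste(paste0(letters[names(selectors)], .level_chars[selectors]),
        collapse = "_")
}

#' Enumerate feature-family combinations
#'
#' Lazily enumerates selector tuples over the six levels (five count levels
#' plus the wildcard) for the eight families, excluding the all-wildcard
#' tuple, in a deterministic lexicographic order (the last family in the
#' canonical order varies fastest, wildcard first, so low-order
#' single-family and pairwise constraints come first). With `prune = TRUE`
#' (the default) combinations whose evaluated column is constant across
#' patients (non-informative) or duplicates an already-emitted column are
#' dropped, and enumeration stops once `cap` combinations have been
#' emitted. With `prune = FALSE` the full census must fit under `cap`,
#' otherwise an overflow error is raised rather than silently truncating.
#'
#' @param levels a `family_levels` object from [assign_levels()].
#' @param prune drop constant and duplicate columns?
#' @param cap maximum number of combinations to emit (>= 1).
#' @param scan_limit maximum number of candidate tuples to examine when
#'   pruning (guards against scanning the full 6^8 census on small data).
#' @param families families to combine (default all eight; a subset gives
#'   a smaller census, e.g. 6^2 - 1 = 35 tuples for two families).
#' @return list with `specs` (data.table: `combo_id`, one selector column
#'   per family, and the disclosure-controlled support count `support` --
#'   `NA` where suppressed) and `columns` (data.table: `patient_id` plus
#'   one 0/1 column per emitted combination).
#' @export
enumerate_combinations <- function(levels, prune = TRUE, cap = 1000L,
                                   scan_limit = 50000L,
                                   families = names(family_order())) {
  stopifnot(cap >= 1, all(families %in% names(family_order())))
  fams <- families
  k <- length(fams)
  lv <- c("x", family_levels())
  total <- 6^k - 1
  if (!prune && total > cap) {
    stop("combination census overflow: ", total, " combinations exceed cap ",
         cap, " with prune = FALSE", call. = FALSE)
  }
  ind <- levels$indicators
  n <- nrow(ind)
  # logical indicator matrix, one column per family level, for fast
  # conjunction evaluation during the scan
  IM <- matrix(FALSE, n, k * 5L,
               dimnames = list(NULL, paste0(rep(fams, each = 5L), "_",
                                            rep(family_levels(), k))))
  for (fam in fams) for (lvl in family_levels()) {
    IM[, paste0(fam, "_", lvl)] <- ind[[paste0("family_", fam, "_", lvl)]] == 1L
  }
  pad <- rep(FALSE, (8L - n %% 8L) %% 8L)
  specs <- list()
  cols <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  n_emitted <- 0L
  idx <- 1
  n_scanned <- 0L
  while (idx <= total && n_emitted < cap &&
         (!prune || n_scanned < scan_limit)) {
    digits <- (idx %/% 6^((k - 1):0)) %% 6
    constrained <- which(digits > 0)
    sel_cols <- paste0(fams[constrained], "_", lv[digits[constrained] + 1])
    col <- rowSums(IM[, sel_cols, drop = FALSE]) == length(sel_cols)
    n_scanned <- n_scanned + 1L
    keep <- TRUE
    if (prune) {
      s <- sum(col)
      if (s == 0L || s == n) {
        keep <- FALSE  # non-informative: single value for all records
      } else {
        key <- jsonlite::base64_enc(packBits(c(col, pad)))
        if (!is.null(seen[[key]])) keep <- FALSE else seen[[key]] <- TRUE
      }
    }
    if (keep) {
      selectors <- setNames(lv[digits + 1], fams)
      n_emitted <- n_emitted + 1L
      specs[[n_emitted]] <- selectors
      cols[[n_emitted]] <- as.integer(col)
      names(cols)[n_emitted] <- combination_id(selectors)
    }
    idx <- idx + 1
  }
  spec_dt <- if (n_emitted) {
    dt <- as.data.table(do.call(rbind, specs))
    dt[, combo_id := names(cols)]
    dt[, support := disclosure_control(vapply(cols, sum, numeric(1)))]
    data.table::setcolorder(dt, c("combo_id", fams, "support"))
    dt
  } else {
    data.table(combo_id = character())
  }
  columns <- data.table(patient_id = ind$patient_id)
  for (nm in names(cols)) columns[, (nm) := cols[[nm]]]
  list(specs = spec_dt, columns = columns)
}
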