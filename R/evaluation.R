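#' Statistical disclosure control for published counts
#'
#' Raw counts are redacted (suppressed) if less than or equal to seven,
#' then rounded to the nearest ten, before any statistic is calculated
#' from them. Rounding is half-up (15 becomes 20), so every published
#' count is either suppressed or a multiple of ten no smaller than ten.
#'
#' @param x non-negative integer count(s).
#' @return integer vector: `NA` where suppressed, otherwise the rounded
#'   count.
#' @examples
#' disclosure_control(c(0, 7, 8, 14, 15, 1155337))
#' @export
disclosure_control <- function(x) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- as.integer(floor(x / 10 + 0.5) * 10)
  out[x <= 7] <- NA_integer_
  names(out) <- names(x)
  out
}

#' Contingency table of a binary feature against caseness
#'
#' Cell conventions: TP = feature present and case, FP = present and
#' control, FN = absent and case, TN = absent and control.
#'
#' @param feature 0/1 vector (feature presence).
#' @param caseness 0/1 vector.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
contingency_table <- function(feature, caseness) {
  stopifnot(length(feature) == length(caseness))
  f <- feature == 1L
  y <- caseness == 1L
  c(TP = sum(f & y), FP = sum(f & !y), FN = sum(!f & y), TN = sum(!f & !y))
}

#' Class balance accuracy
#'
#' The lower bound of the average sensitivity and average positive
#' predictive value:
#' `0.5 * (TP / min(TP + FN, TP + FP) + TN / min(TN + FP, TN + FN))`.
#' Preferred over overall accuracy when the outcome is rare and weakly
#' separable.
#'
#' @param tp,fp,fn,tn contingency cells (`NA` for suppressed cells).
#' @return CBA in \[0, 1\], or `NA` when a needed cell is suppressed or a
#'   denominator is zero.
#' @export
class_balance_accuracy <- function(tp, fp, fn, tn) {
  if (anyNA(c(tp, fp, fn, tn))) return(NA_real_)
  d1 <- min(tp + fn, tp + fp)
  d2 <- min(tn + fp, tn + fn)
  if (d1 == 0 || d2 == 0) return(NA_real_)
  0.5 * (tp / d1 + tn / d2)
}

#' Odds ratio of caseness given feature presence
#'
#' `(TP * TN) / (FP * FN)`: the multiplicative change in the odds of
#' caseness associated with the presence of the feature, in the context of
#' all unmeasured confounding. With a zero FP or FN cell the ratio is
#' infinite and is reported as `Inf` (unavailable-with-direction) unless
#' the Haldane continuity correction (+0.5 per cell) is requested.
#'
#' @param tp,fp,fn,tn contingency cells (`NA` for suppressed cells).
#' @param correction add 0.5 to every cell?
#' @return odds ratio, `Inf`, or `NA`.
#' @export
odds_ratio <- function(tp, fp, fn, tn, correction = FALSE) {
  if (anyNA(c(tp, fp, fn, tn))) return(NA_real_)
  if (correction) {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  if (fp == 0 || fn == 0) return(Inf)
  (tp * tn) / (fp * fn)
}

#' Predictive values and prevalence of a binary feature
#'
#' PPV = TP / (TP + FP); NPV = TN / (TN + FN); prevalence per 1,000 =
#' `1000 * (TP + FP) / (TP + FP + FN + TN)` (the proportion of records
#' meeting the definition of the feature, scaled to per-1,000).
#'
#' @param tp,fp,fn,tn contingency cells (`NA` for suppressed cells).
#' @return named numeric vector `c(ppv, npv, prevalence_per_1000)` with
#'   `NA` where a denominator is zero or a needed cell is suppressed.
#' @export
ppv_npv_prevalence <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  ppv <- if (anyNA(c(tp, fp)) || tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (anyNA(c(tn, fn)) || tn + fn == 0) NA_real_ else tn / (tn + fn)
  prev <- if (is.na(total) || total == 0) NA_real_ else
    1000 * (tp + fp) / total
  c(ppv = ppv, npv = npv, prevalence_per_1000 = prev)
}

#' Evaluate binary feature sets against caseness
#'
#' Computes the contingency table of each binary feature set against the
#' caseness variable and the evaluation statistics (prevalence per 1,000,
#' class balance accuracy, odds ratio, PPV, NPV). Statistics are reported
#' twice: once from the raw cells (`*_raw`) and once from the
#' disclosure-controlled cells (the publishable set, computed only after
#' suppression and rounding). Any statistic needing a suppressed cell is
#' `NA` rather than imputed.
#'
#' @param columns data.table with `patient_id` plus binary feature columns.
#' @param caseness 0/1 vector aligned with `columns` rows.
#' @param feature_ids which columns to evaluate (default: all but
#'   `patient_id`).
#' @param or_correction apply the continuity correction in [odds_ratio()]?
#' @return data.table with one row per feature: raw and controlled cells
#'   and both sets of statistics.
#' @export
evaluate_feature_sets <- function(columns, caseness, feature_ids = NULL,
                                  or_correction = FALSE) {
  if (is.null(feature_ids)) {
    feature_ids <- setdiff(names(columns), "patient_id")
  }
  y <- as.integer(caseness)
  rows <- lapply(feature_ids, function(fid) {
    cells <- contingency_table(columns[[fid]], y)
    sdc <- disclosure_control(cells)
    stats_for <- function(ct) {
      pn <- ppv_npv_prevalence(ct[1], ct[2], ct[3], ct[4])
      c(prevalence_per_1000 = unname(pn["prevalence_per_1000"]),
        cba = class_balance_accuracy(ct[1], ct[2], ct[3], ct[4]),
        odds_ratio = odds_ratio(ct[1], ct[2], ct[3], ct[4],
                                correction = or_correction),
        ppv = unname(pn["ppv"]), npv = unname(pn["npv"]))
    }
    raw <- stats_for(as.numeric(cells))
    ctl <- stats_for(as.numeric(sdc))
    data.table(
      feature_id = fid,
      tp_raw = cells[["TP"]], fp_raw = cells[["FP"]],
      fn_raw = cells[["FN"]], tn_raw = cells[["TN"]],
      tp = sdc[[1]], fp = sdc[[2]], fn = sdc[[3]], tn = sdc[[4]],
      prevalence_per_1000 = ctl[["prevalence_per_1000"]],
      cba = ctl[["cba"]], odds_ratio = ctl[["odds_ratio"]],
      ppv = ctl[["ppv"]], npv = ctl[["npv"]],
      prevalence_per_1000_raw = raw[["prevalence_per_1000"]],
      cba_raw = raw[["cba"]], odds_ratio_raw = raw[["odds_ratio"]],
      ppv_raw = raw[["ppv"]], npv_raw = raw[["npv"]]
    )
  })
  rbindlist(rows)
}
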