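make_fm <- function(n = 400, seed = 14) {
  cohort <- generate_cohort(cohort_config(n_patients = n, seed = seed))
  labels <- build_study_population(cohort)
  build_feature_matrix(cohort, labels)
}

test_that("family level indicators satisfy their invariants", {
  fm <- make_fm()
  lv <- assign_levels(fm)
  a <- lv$assignments
  expect_true(all(a$None == (a$component_count == 0)))
  expect_true(all(a$NotNone == (a$component_count >= 1)))
  expect_true(all(xor(a$None, a$NotNone)))
  fsm <- a$Few + a$Some + a$Many
  expect_true(all(fsm[a$component_count >= 1] == 1))
  expect_true(all(fsm[a$component_count == 0] == 0))
  expect_true(all(a$NotNone == (a$Few | a$Some | a$Many)))
})

test_that("level assignment matches a brute-force re-evaluation of the cutpoint rules", {
  fm <- make_fm(seed = 15)
  lv <- assign_levels(fm)
  cp <- lv$cutpoints
  a <- lv$assignments
  for (fam in unique(a$family)) {
    qs <- cp[cp$family == fam, ]
    af <- a[a$family == fam, ]
    cc <- af$component_count
    expect_equal(af$Few, cc >= 1 & cc <= qs$q_low)
    expect_equal(af$Some, cc > qs$q_low & cc <= qs$q_high)
    expect_equal(af$Many, cc > qs$q_high)
    # a patient at the maximum observed count is Many (when counts vary)
    if (max(cc) > qs$q_high) {
      expect_true(all(af$Many[cc == max(cc)]))
    }
  }
  # explicit cutpoints are honoured and validated
  expect_error(assign_levels(fm, cutpoints = data.frame(
    family = cp$family, q_low = 0, q_high = 1)), "q_low")
})

test_that("a family with no member features is a configuration error", {
  fm <- make_fm(seed = 16)
  fm$meta <- fm$meta[fm$meta$family != "Treatment", ]
  expect_error(assign_levels(fm), "Treatment")
})

test_that("combination evaluation is the stated conjunction with wildcards", {
  fm <- make_fm(seed = 17)
  lv <- assign_levels(fm)
  fams <- names(mhscreen:::family_order())
  # single-constraint combination equals that family's level column
  sel <- setNames(rep("x", 8), fams)
  sel["Treatment"] <- "NotNone"
  expect_equal(evaluate_combination(sel, lv),
               lv$indicators[["family_Treatment_NotNone"]])
  # Antecedent present, Concurrent absent, rest irrelevant
  sel2 <- setNames(rep("x", 8), fams)
  sel2["Antecedent"] <- "NotNone"
  sel2["Concurrent"] <- "None"
  col <- evaluate_combination(sel2, lv)
  a <- lv$assignments
  ant <- a[a$family == "Antecedent", ][["component_count"]]
  con <- a[a$family == "Concurrent", ][["component_count"]]
  expect_equal(col, as.integer(ant >= 1 & con == 0))
  # random specs vs a brute-force conjunction oracle
  set.seed(18)
  for (rep in 1:25) {
    sel3 <- setNames(sample(c("x", "None", "NotNone", "Few", "Some", "Many"),
                            8, replace = TRUE), fams)
    if (all(sel3 == "x")) sel3["ServiceUse"] <- "None"
    want <- rep(TRUE, nrow(lv$indicators))
    for (fam in fams) {
      if (sel3[[fam]] != "x") {
        want <- want & (lv$indicators[[paste0("family_", fam, "_",
                                              sel3[[fam]])]] == 1L)
      }
    }
    expect_equal(evaluate_combination(sel3, lv), as.integer(want))
  }
  expect_error(evaluate_combination(setNames(rep("x", 8), fams), lv),
               "wildcard")
})

test_that("combination enumeration counts, prunes, and errors as specified", {
  fm <- make_fm(seed = 19)
  lv <- assign_levels(fm)
  # 2 families without pruning: 6^2 - 1 = 35 combinations
  res <- enumerate_combinations(lv, prune = FALSE, cap = 100,
                                families = c("Treatment", "Concurrent"))
  expect_equal(nrow(res$specs), 35L)
  expect_equal(ncol(res$columns) - 1L, 35L)
  # overflow with prune off is an explicit error, not silent truncation
  expect_error(enumerate_combinations(lv, prune = FALSE, cap = 10,
                                      families = c("Treatment", "Concurrent")),
               "overflow")
  # pruned enumeration emits no constant and no duplicate columns
  res2 <- enumerate_combinations(lv, prune = TRUE, cap = 150)
  M <- as.matrix(res2$columns[, -1])
  expect_true(all(colSums(M) > 0 & colSums(M) < nrow(M)))
  expect_false(anyDuplicated(t(M)) > 0)
  # pruned output equals brute-force enumeration + filtering in the same
  # order over a small census
  res3 <- enumerate_combinations(lv, prune = TRUE, cap = 1000,
                                 families = c("Treatment", "Inconsistency"))
  lvs <- c("x", "None", "NotNone", "Few", "Some", "Many")
  seen <- list()
  want_ids <- character(0)
  for (i in lvs) for (j in lvs) {
    if (i == "x" && j == "x") next
  }
  # brute force in the same digit order (last family fastest)
  fams2 <- c("Treatment", "Inconsistency")
  for (idx in 1:(36 - 1)) {
    digits <- c(idx %/% 6, idx %% 6)
    sel <- setNames(lvs[digits + 1], fams2)
    col <- rep(TRUE, nrow(lv$indicators))
    for (fam in fams2) {
      if (sel[[fam]] != "x") {
        col <- col & (lv$indicators[[paste0("family_", fam, "_",
                                            sel[[fam]])]] == 1L)
      }
    }
    s <- sum(col)
    if (s == 0 || s == length(col)) next
    key <- paste(as.integer(col), collapse = "")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    want_ids <- c(want_ids, mhscreen:::combination_id(sel))
  }
  expect_equal(res3$specs$combo_id, want_ids)
})

test_that("tightening a combination shrinks its TRUE-set", {
  fm <- make_fm(seed = 20)
  lv <- assign_levels(fm)
  fams <- names(mhscreen:::family_order())
  set.seed(21)
  for (rep in 1:20) {
    sel <- setNames(rep("x", 8), fams)
    sel[sample(8, 2)] <- sample(c("None", "NotNone", "Few"), 2,
                                replace = TRUE)
    if (all(sel == "x")) next
    loose <- evaluate_combination(sel, lv)
    wild <- which(sel == "x")
    tight_fam <- fams[sample(wild, 1)]
    sel[tight_fam] <- sample(c("None", "NotNone", "Few", "Some", "Many"), 1)
    tight <- evaluate_combination(sel, lv)
    expect_true(all(tight <= loose))
  }
})
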