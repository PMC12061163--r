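test_that("binary entropy: maximum, degenerate, domain", {
  expect_equal(binary_entropy(0.5), log(2))
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_error(binary_entropy(-0.1), "probability")
  expect_error(binary_entropy(1.1), "probability")
  # symmetric and concave around 1/2
  expect_equal(binary_entropy(0.2), binary_entropy(0.8))
})

test_that("plug-in MI: self-information, exact independence, formula oracle", {
  y <- rep(c(0L, 1L), c(60, 20))
  # x identical to y: MI equals the full entropy (scaled MI would be 1)
  expect_equal(plugin_mi(y, y), binary_entropy(0.25))
  # exact product structure by blocked construction: MI is exactly 0
  x <- rep(c(0, 1, 0, 1), c(45, 15, 15, 5))  # x independent of y by counts
  y2 <- rep(c(0, 0, 1, 1), c(45, 15, 15, 5))
  expect_equal(plugin_mi(x, y2), 0)
  # hand-evaluated 2x2 oracle on (TP, FP, FN, TN) = (20, 80, 30, 870)
  xx <- rep(c(1, 1, 0, 0), c(20, 80, 30, 870))
  yy <- rep(c(1, 0, 1, 0), c(20, 80, 30, 870))
  expect_equal(plugin_mi(xx, yy), oracle_mi_2x2(20, 80, 30, 870),
               tolerance = 1e-12)
  # invariant to relabelling of categories
  expect_equal(plugin_mi(xx, yy),
               plugin_mi(c("b", "a")[xx + 1], c("z", "q")[yy + 1]))
  # constant x: zero information
  expect_equal(plugin_mi(rep(1, length(yy)), yy), 0)
})

test_that("plug-in MI never exceeds the caseness entropy", {
  set.seed(31)
  for (rep in 1:50) {
    n <- 500
    y <- rbinom(n, 1, 0.1)
    x <- rbinom(n, 1, plogis(-2 + 2 * y))
    expect_lte(plugin_mi(x, y), binary_entropy(mean(y)) + 1e-12)
  }
})

test_that("knn mixed MI is near zero under independence", {
  set.seed(32)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, 0.3)
  est <- knn_mixed_mi(x, y, k = 3, n_runs = 5, seed = 1)
  expect_lt(est$mi, 0.02)
  expect_gte(est$mi, 0)
})

test_that("knn mixed MI recovers the Gaussian-mixture truth", {
  set.seed(33)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n, 3 * y, 1)
  truth <- oracle_gaussian_mixture_mi()
  est <- knn_mixed_mi(x, y, k = 3, n_runs = 5, seed = 2)
  expect_lt(abs(est$mi - truth), 0.05)
})

test_that("knn MI on a discretised binary feature agrees with the plug-in estimator", {
  set.seed(34)
  n <- 5000
  y <- rbinom(n, 1, 0.3)
  x <- rbinom(n, 1, plogis(-1 + 1.5 * y))
  ref <- plugin_mi(x, y)
  est <- knn_mixed_mi(as.numeric(x), y, k = 3, n_runs = 20, seed = 3)
  expect_lt(abs(est$mi - ref), 0.02)
})

test_that("knn MI skips features with a class at or below k members", {
  x <- rnorm(50)
  y <- c(rep(0, 47), rep(1, 3))
  est <- knn_mixed_mi(x, y, k = 3, n_runs = 2, seed = 1)
  expect_true(is.na(est$mi))
})

test_that("ranking sorts by scaled MI with lexicographic ties and excludes constants", {
  set.seed(35)
  n <- 300
  y <- rbinom(n, 1, 0.2)
  columns <- data.table::data.table(
    patient_id = sprintf("P%03d", 1:n),
    strong = as.integer(y == 1 & runif(n) < 0.9),
    weak = rbinom(n, 1, 0.5),
    aaa_dup = y,         # ties: identical to zzz_dup
    zzz_dup = y,
    flat = 1L
  )
  meta <- data.table::data.table(
    feature_id = c("strong", "weak", "aaa_dup", "zzz_dup", "flat"),
    value_type = "binary", set_type = "component")
  r <- rank_feature_sets(columns, meta, y)
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_false("flat" %in% r$feature_id)
  expect_equal(attr(r, "n_non_informative"), 1L)
  # equal estimates: deterministic lexicographic order
  ia <- r$rank[r$feature_id == "aaa_dup"]
  iz <- r$rank[r$feature_id == "zzz_dup"]
  expect_equal(iz, ia + 1L)
  # scaled MI of the perfect duplicates of caseness is 100%
  expect_equal(r$mi_scaled_pct[r$feature_id == "aaa_dup"], 100)
  expect_true(all(diff(r$mi_scaled_pct) <= 1e-12))
  # single feature gets rank 1
  r1 <- rank_feature_sets(columns[, c("patient_id", "strong"), with = FALSE],
                          meta[meta$feature_id == "strong", ], y)
  expect_equal(r1$rank, 1L)
})

test_that("a fixed seed fixes the full ranking byte-for-byte", {
  set.seed(36)
  n <- 400
  y <- rbinom(n, 1, 0.25)
  columns <- data.table::data.table(
    patient_id = sprintf("P%03d", 1:n),
    cont1 = rnorm(n, y, 2),
    cont2 = rexp(n) + 0.3 * y,
    bin1 = rbinom(n, 1, 0.3 + 0.2 * y)
  )
  meta <- data.table::data.table(
    feature_id = c("cont1", "cont2", "bin1"),
    value_type = c("continuous", "continuous", "binary"),
    set_type = "component")
  r1 <- rank_feature_sets(columns, meta, y, n_runs = 3, seed = 99)
  r2 <- rank_feature_sets(columns, meta, y, n_runs = 3, seed = 99)
  expect_identical(r1, r2)
})
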