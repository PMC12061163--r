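test_that("quarterly entropy hits its analytic limits", {
  year <- rep(2018:2020, each = 12)
  month <- rep(1:12, 3)
  # all non-attendance in a single quarter each year: entropy 0
  dna_point <- ifelse(month <= 3, 2L, 0L)
  expect_equal(avg_quarterly_entropy(dna_point, year, month), 0)
  # uniform over quarters: normalised entropy 1
  dna_unif <- rep(1L, 36)
  expect_equal(avg_quarterly_entropy(dna_unif, year, month), 1)
  # a year with no non-attendance contributes 0
  dna_mixed <- ifelse(year == 2019, 0L, 1L)
  expect_equal(avg_quarterly_entropy(dna_mixed, year, month), 2 / 3)
  # less than one full calendar year: missing
  expect_true(is.na(avg_quarterly_entropy(1:5, rep(2020, 5), 1:5)))
})

test_that("quarterly entropy matches the per-year formula oracle on random series", {
  set.seed(202)
  for (rep in 1:200) {
    n_years <- sample(1:4, 1)
    start_month <- sample(1:12, 1)
    len <- sample(8:(12 * n_years + 6), 1)
    mid <- seq(from = (2016 * 12 + start_month - 1), length.out = len)
    year <- mid %/% 12
    month <- mid %% 12 + 1
    dna <- rpois(len, 0.6)
    expect_equal(avg_quarterly_entropy(dna, year, month),
                 oracle_quarterly(dna, year, month))
  }
})

test_that("spectral entropy: periodic near 0, white noise near its Monte-Carlo mean, bounded", {
  # pure sinusoid with an integer number of cycles: single spectral bin
  x <- sin(2 * pi * (1:60) / 12)
  expect_lt(spectral_entropy(x), 1e-6)
  # white noise: mean normalised entropy matches a Monte-Carlo oracle for a
  # flat expected spectrum
  set.seed(303)
  mc_oracle <- mean(replicate(300, oracle_spectral(rnorm(60))))
  binary_mean <- mean(replicate(300, spectral_entropy(rbinom(60, 1, 0.3))))
  expect_lt(abs(binary_mean - mc_oracle), 0.05)
  expect_gt(mc_oracle, 0.8)
  # bounds and degenerate inputs
  set.seed(304)
  for (rep in 1:100) {
    v <- spectral_entropy(rpois(sample(24:80, 1), 0.5))
    if (!is.na(v)) expect_true(v >= 0 && v <= 1)
  }
  expect_true(is.na(spectral_entropy(rep(2, 60))))   # constant: zero power
  expect_true(is.na(spectral_entropy(rnorm(10))))    # too short
})

test_that("spectral entropy equals the direct-DFT oracle on random series", {
  set.seed(305)
  for (rep in 1:200) {
    x <- rpois(sample(24:72, 1), 0.7)
    if (sd(x) == 0) next
    expect_equal(spectral_entropy(x), oracle_spectral(x), tolerance = 1e-10)
  }
})

test_that("sample entropy: regularity limits and brute-force agreement", {
  # constant series with an explicit positive tolerance: perfect regularity
  expect_equal(sample_entropy(rep(3, 30), r = 0.5), 0)
  # constant series under the default r = 0.2 * sd: tolerance collapses, NA
  expect_true(is.na(sample_entropy(rep(3, 30))))
  # alternating series vs the O(n^2) template-matching oracle
  x <- rep(c(0, 1), 20)
  expect_equal(sample_entropy(x, m = 2, r = 0.2 * sd(x)),
               oracle_sampen(x, 2, 0.2 * sd(x)))
  # translation invariance of Chebyshev distances
  y <- rpois(50, 2)
  expect_equal(sample_entropy(y), sample_entropy(y + 7))
  # too short: missing
  expect_true(is.na(sample_entropy(c(1, 2, 3), m = 2)))
})

test_that("sample entropy matches the brute-force oracle on random short series", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(10:40, 1)
    m <- sample(1:3, 1)
    x <- rpois(n, sample(1:3, 1))
    if (sd(x) == 0) next
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, m = m, r = r), oracle_sampen(x, m, r),
                 info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("active information: constant zero, periodic exact, iid near the permutation null", {
  # constant indicator: zero marginal entropy, MI 0
  expect_equal(active_information(rep(1, 20)), 0)
  expect_equal(active_information(rep(0, 20)), 0)
  # strictly periodic pattern with period <= 3: equals the plug-in value
  # from the exact pattern-frequency table
  x <- rep(c(1, 0, 0), 10)
  expect_equal(active_information(x), oracle_active_info(x))
  x2 <- rep(c(1, 0), 12)
  expect_equal(active_information(x2), oracle_active_info(x2))
  # period-2 alternation is perfectly predictable from its history: the MI
  # equals the marginal entropy of the next month (log 2 here)
  expect_equal(active_information(x2), binary_entropy(0.5))
  # too short: missing
  expect_true(is.na(active_information(rep(c(0, 1), 7))))
})

test_that("active information matches the enumeration oracle on random series", {
  set.seed(505)
  for (rep in 1:200) {
    x <- rbinom(sample(15:30, 1), 1, runif(1, 0.2, 0.8))
    expect_equal(active_information(x), oracle_active_info(x))
  }
})

test_that("active information of iid months is small, with bias bounded by the permutation null", {
  set.seed(606)
  vals <- numeric(150)
  nulls <- numeric(150)
  for (i in 1:150) {
    x <- rbinom(15, 1, 0.4)
    vals[i] <- active_information(x)
    # permutation null for the same series: destroys temporal structure
    # while keeping the marginal, so it carries the same plug-in bias
    nulls[i] <- mean(replicate(10, active_information(sample(x))))
  }
  expect_true(all(vals >= 0))
  # expectation near 0 in the sense that it does not exceed the
  # small-sample bias measured by the permutation null
  se <- sqrt(var(vals) / 150 + var(nulls) / 150)
  expect_lt(mean(vals), mean(nulls) + 3 * se)
  # and the bias itself is below the (K-1)(L-1)/(2N) plug-in bias scale
  expect_lt(mean(vals), 2 * (8 - 1) * (2 - 1) / (2 * 12))
})

test_that("normalised entropies stay in [0, 1] and sample entropy is non-negative", {
  set.seed(707)
  for (rep in 1:100) {
    n <- sample(24:72, 1)
    dna <- rpois(n, 0.5)
    se <- spectral_entropy(dna)
    if (!is.na(se)) expect_true(se >= 0 && se <= 1)
    ai <- active_information(as.integer(dna > 0))
    if (!is.na(ai)) expect_gte(ai, 0)
    sam <- sample_entropy(rpois(n, 2))
    if (!is.na(sam)) expect_gte(sam, 0)
  }
})
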