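#' Shannon entropy of a discrete distribution (nats)
#'
#' @param p vector of probabilities or non-negative weights (normalised
#'   internally); zero cells contribute zero.
#' @return entropy in nats.
#' @keywords internal
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("negative probabilities", call. = FALSE)
  s <- sum(p)
  if (s == 0) return(0)
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sample entropy of a numeric series
#'
#' Standard sample entropy: the negative log of the conditional probability
#' that two sequences matching for `m` points (Chebyshev distance within
#' tolerance `r`) also match for `m + 1` points, excluding self-matches.
#' Lower values indicate a more regular series.
#'
#' @param x numeric series (e.g. monthly appointment counts).
#' @param m embedding (template) length.
#' @param r tolerance; defaults to `0.2 * sd(x)`. With the default, a
#'   constant series has `r = 0` and the result is `NA`; with an explicit
#'   `r > 0` a constant series returns 0 (perfect regularity).
#' @return sample entropy in nats, or `NA` when undefined (series shorter
#'   than `m + 2`, zero tolerance, or no template matches).
#' @examples
#' sample_entropy(rep(c(0, 1), 30))
#' sample_entropy(rnorm(60))
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  x <- as.numeric(x)
  if (anyNA(x) || length(x) < m + 2L) return(NA_real_)
  if (!is.finite(r) || r <= 0) return(NA_real_)
  sampen_cpp(x, as.integer(m), r)
}

#' Normalised spectral entropy of a series
#'
#' Shannon entropy of the normalised power spectrum of the mean-centred
#' series (positive frequencies only), scaled by the log of the number of
#' spectral bins so the result lies in \[0, 1\]. A single dominant periodic
#' component gives values near 0; white noise gives values near 1.
#'
#' @param x numeric series (monthly non-attendance counts); needs at least
#'   `min_length` observations and must not be constant.
#' @param min_length minimum series length.
#' @return normalised spectral entropy in \[0, 1\], or `NA` when undefined.
#' @examples
#' spectral_entropy(sin(2 * pi * (1:60) / 12))  # near 0
#' @export
spectral_entropy <- function(x, min_length = 24L) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x) || n < min_length) return(NA_real_)
  z <- x - mean(x)
  if (all(z == 0)) return(NA_real_)
  pw <- Mod(fft(z))^2
  # positive frequencies: indices 2 .. floor(n/2) + 1 (Nyquist included
  # when n is even)
  pw <- pw[2:(n %/% 2 + 1)]
  if (sum(pw) <= 0) return(NA_real_)
  shannon_entropy(pw) / log(length(pw))
}

#' Average entropy of quarterly non-attendance
#'
#' For each full calendar year covered by the series, the four quarterly
#' non-attendance counts are normalised to proportions and their Shannon
#' entropy is taken in nats and scaled by `ln 4`, so each year scores in
#' \[0, 1\] (0 = all non-attendance in one quarter, 1 = uniform over
#' quarters; a year with no non-attendance scores 0). The feature is the
#' arithmetic mean over full years.
#'
#' @param dna monthly non-attendance counts.
#' @param year,month calendar year and month (1--12) for each entry of
#'   `dna`.
#' @return mean normalised quarterly entropy in \[0, 1\], or `NA` if the
#'   series covers no full calendar year.
#' @export
avg_quarterly_entropy <- function(dna, year, month) {
  stopifnot(length(dna) == length(year), length(dna) == length(month))
  if (!length(dna)) return(NA_real_)
  months_per_year <- tapply(month, year, function(m) length(unique(m)))
  full_years <- as.integer(names(months_per_year)[months_per_year == 12L])
  if (!length(full_years)) return(NA_real_)
  per_year <- vapply(full_years, function(y) {
    sel <- year == y
    q <- tapply(dna[sel], (month[sel] - 1L) %/% 3L, sum)
    q <- as.numeric(q)
    if (sum(q) == 0) 0 else shannon_entropy(q) / log(4)
  }, numeric(1))
  mean(per_year)
}

#' Active information of a binary monthly series
#'
#' Predictability of the most recent months of non-attendance from their own
#' recent past: the plug-in mutual information (nats) between the
#' `recent_months`-long history pattern and the following month's indicator,
#' estimated over all sliding windows whose history lies within the
#' preceding `history_months`. Larger values mean the latest pattern of
#' non-attendance is consistent with the pattern of the preceding year.
#'
#' @param x binary indicator series (1 = any non-attendance that month),
#'   most recent value last.
#' @param history_months number of sliding windows (the preceding-year
#'   span).
#' @param recent_months history pattern length.
#' @return plug-in mutual information in nats (>= 0), or `NA` if the series
#'   is shorter than `history_months + recent_months`.
#' @export
active_information <- function(x, history_months = 12L, recent_months = 3L) {
  x <- as.integer(x != 0)
  need <- history_months + recent_months
  if (anyNA(x) || length(x) < need) return(NA_real_)
  x <- x[(length(x) - need + 1L):length(x)]
  idx <- seq_len(history_months)
  pat <- vapply(idx, function(p)
    sum(x[p:(p + recent_months - 1L)] * 2^((recent_months - 1L):0)),
    numeric(1))
  nxt <- x[idx + recent_months]
  plugin_mi(pat, nxt)
}
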