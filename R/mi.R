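#' Binary entropy in nats
#'
#' Entropy of a Bernoulli(p) variable, `-p log p - (1 - p) log(1 - p)`,
#' with `0 log 0 = 0`. The entropy of the caseness variable is the scaling
#' denominator for all mutual-information scores.
#'
#' @param p probability (vectorised).
#' @return entropy in nats.
#' @examples
#' binary_entropy(0.5)            # log(2)
#' binary_entropy(c(0, 1))        # 0 0
#' @export
binary_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must be a probability in [0, 1]", call. = FALSE)
  }
  term <- function(q) ifelse(q == 0, 0, -q * log(q))
  term(p) + term(1 - p)
}

#' Plug-in mutual information between two discrete variables
#'
#' Mutual information in nats computed directly from the empirical joint
#' frequency table: `sum p(x, y) log[p(x, y) / (p(x) p(y))]`.
#' Deterministic; a constant `x` gives exactly 0.
#'
#' @param x,y discrete vectors of equal length with no missing values.
#' @return mutual information in nats (>= 0).
#' @examples
#' plugin_mi(c(0, 0, 1, 1), c(0, 0, 1, 1))  # log(2)
#' @export
plugin_mi <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values must be handled upstream",
                                 call. = FALSE)
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / e[pos]))
}

# vectorised plug-in MI over many 2x2 tables given joint counts
# (x=1,y=1), (x=1,y=0), (x=0,y=1), (x=0,y=0)
.mi_2x2_vec <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  term <- function(nxy, nx, ny) {
    out <- rep(0, length(nxy))
    pos <- nxy > 0
    out[pos] <- (nxy[pos] / n[pos]) *
      log(nxy[pos] * n[pos] / (nx[pos] * ny[pos]))
    out
  }
  n1x <- n11 + n10
  n0x <- n01 + n00
  nx1 <- n11 + n01
  nx0 <- n10 + n00
  term(n11, n1x, nx1) + term(n10, n1x, nx0) +
    term(n01, n0x, nx1) + term(n00, n0x, nx0)
}

# one evaluation of the nearest-neighbour mixed discrete-continuous MI
# estimator (Ross 2014) for 1-d x and discrete y, after ties have been
# broken by jitter. Follows the convention of the field's standard
# implementation: the radius is the distance to the k-th nearest same-class
# neighbour and m_i counts all points strictly within that radius
# (including the point itself).
.ross_mi_1d <- function(x, y, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  radius <- numeric(n)
  kvec <- integer(n)
  for (cl in unique(ys)) {
    idx <- which(ys == cl)
    nc <- length(idx)
    kc <- min(k, nc - 1L)
    xc <- xs[idx]
    # in sorted 1-d data the kc nearest neighbours form a contiguous window:
    # with j taken from the right and kc - j from the left, the kc-th NN
    # distance is the larger window extreme; minimise over j
    right <- lapply(0:kc, function(j) {
      out <- rep(Inf, nc)
      if (j == 0L) out[] <- 0 else
        out[1:(nc - j)] <- xc[(1L + j):nc] - xc[1:(nc - j)]
      out
    })
    left <- lapply(0:kc, function(j) {
      out <- rep(Inf, nc)
      if (j == 0L) out[] <- 0 else
        out[(1L + j):nc] <- xc[(1L + j):nc] - xc[1:(nc - j)]
      out
    })
    d_k <- rep(Inf, nc)
    for (j in 0:kc) {
      d_k <- pmin(d_k, pmax(right[[j + 1L]], left[[kc - j + 1L]]))
    }
    radius[idx] <- d_k
    kvec[idx] <- kc
  }
  # count points strictly within the radius; findInterval works on
  # positions, so correct the interval ends by direct distance comparison
  # (the k-th same-class neighbour lies at exactly the radius and must be
  # excluded regardless of rounding in xs + radius)
  hi <- findInterval(xs + radius, xs, left.open = TRUE)
  lo <- findInterval(xs - radius, xs) + 1L
  for (pass in 1:2) {
    drop_hi <- hi >= 1L & (xs[pmax(hi, 1L)] - xs >= radius)
    hi[drop_hi] <- hi[drop_hi] - 1L
    add_hi <- hi < n & (xs[pmin(hi + 1L, n)] - xs < radius)
    hi[add_hi] <- hi[add_hi] + 1L
    drop_lo <- lo <= n & (xs - xs[pmin(lo, n)] >= radius)
    lo[drop_lo] <- lo[drop_lo] + 1L
    add_lo <- lo > 1L & (xs - xs[pmax(lo - 1L, 1L)] < radius)
    lo[add_lo] <- lo[add_lo] - 1L
  }
  m <- hi - lo + 1L
  # exact duplicates can survive the jitter when the jitter amplitude is
  # below one ulp of x; a zero radius then has an empty open interval. In
  # that case count the tie cluster itself (distance <= 0), the closed-
  # interval convention of the standard implementation at zero radius.
  if (any(radius == 0)) {
    rl <- rle(xs)
    ties <- rep(rl$lengths, rl$lengths)
    zero <- radius == 0
    m[zero] <- ties[zero]
  }
  nclass <- table(ys)[as.character(ys)]
  digamma(n) - mean(digamma(as.numeric(nclass))) +
    mean(digamma(kvec)) - mean(digamma(m))
}

#' Nearest-neighbour mixed discrete-continuous mutual information
#'
#' Estimates the mutual information in nats between a continuous variable
#' and a discrete class label with the digamma-form k-nearest-neighbour
#' estimator of Ross (2014): `psi(N) - <psi(N_class)> + psi(k) - <psi(m_i)>`
#' where `m_i` counts all-sample neighbours within the distance of the
#' k-th same-class neighbour. Because ties are broken by a tiny symmetric
#' random jitter, the estimator is stochastic; the reported estimate is the
#' arithmetic mean of `n_runs` runs (per-run values are retained). The mean
#' is clamped at 0 from below (the estimator can be slightly negative under
#' independence).
#'
#' @param x continuous (or many-valued count) vector.
#' @param y discrete class vector; every class must have at least `k + 1`
#'   members, otherwise the estimate is `NA` and the feature should be
#'   flagged.
#' @param k number of nearest neighbours.
#' @param n_runs number of jittered runs averaged.
#' @param seed integer seed; run `r` uses `seed + r` so the full set of
#'   runs is reproducible.
#' @param jitter_scale relative scale of the tie-breaking jitter, applied
#'   to the interquartile range of `x` (or its standard deviation when the
#'   IQR is 0).
#' @return list with `mi` (clamped mean estimate, nats), `runs` (raw
#'   per-run values), `k`, and `n` (sample size).
#' @export
knn_mixed_mi <- function(x, y, k = 3L, n_runs = 20L, seed = NULL,
                         jitter_scale = 1e-10) {
  stopifnot(length(x) == length(y), n_runs >= 1)
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep])
  y <- y[keep]
  tab <- table(y)
  if (length(tab) < 2L || any(tab <= k)) {
    return(list(mi = NA_real_, runs = rep(NA_real_, n_runs), k = k,
                n = length(x)))
  }
  s <- stats::IQR(x)
  if (s == 0) s <- sd(x)
  if (s == 0) s <- 1
  runs <- vapply(seq_len(n_runs), function(r) {
    if (!is.null(seed)) set.seed(as.integer((seed + r) %% .Machine$integer.max))
    xj <- x + jitter_scale * s * (runif(length(x)) - 0.5)
    .ross_mi_1d(xj, y, k)
  }, numeric(1))
  list(mi = max(0, mean(runs)), runs = runs, k = k, n = length(x))
}

#' Rank feature sets by scaled mutual information
#'
#' Computes the two-way mutual information between every feature-set column
#' and the caseness variable, scales it by the entropy of the caseness
#' variable, and ranks all informative feature sets (1 = most informative,
#' ties broken lexicographically by feature id). Binary and low-cardinality
#' count columns use the deterministic plug-in estimator; continuous and
#' high-cardinality count columns use the mean of `n_runs` runs of the
#' nearest-neighbour mixed estimator on complete cases. Columns that take a
#' single value (non-informative) are excluded and counted.
#'
#' @param columns data.table with `patient_id` plus one column per feature
#'   set.
#' @param meta data.table with `feature_id`, `value_type` (binary, count,
#'   continuous), `set_type` (component, family, combination) for every
#'   column.
#' @param caseness logical/0-1 vector aligned with `columns` rows.
#' @param k,n_runs,seed nearest-neighbour estimator settings.
#' @param count_discrete_max_levels counts with at most this many distinct
#'   values use the plug-in estimator.
#' @return data.table of class `ranked_feature_sets`: `feature_id`,
#'   `set_type`, `value_type`, `estimator`, `n_used`, `mi_nats`,
#'   `mi_scaled_pct`, `rank`, sorted by rank. Attributes:
#'   `caseness_entropy_nats`, `n_non_informative`, `n_skipped` (small-class
#'   continuous features).
#' @export
rank_feature_sets <- function(columns, meta, caseness, k = 3L, n_runs = 20L,
                              seed = NULL, count_discrete_max_levels = 30L) {
  meta <- as.data.table(meta)
  y <- as.integer(caseness)
  stopifnot(nrow(columns) == length(y))
  h_case <- binary_entropy(mean(y))
  if (h_case == 0) warning("caseness is constant; all scaled MI undefined")

  ids <- meta$feature_id
  stopifnot(all(ids %in% names(columns)))
  n_noninf <- 0L
  n_skipped <- 0L
  rows <- vector("list", length(ids))

  # fast path: all binary columns at once via joint counts
  bin_ids <- meta[value_type == "binary", feature_id]
  bin_res <- NULL
  if (length(bin_ids)) {
    M <- as.matrix(columns[, bin_ids, with = FALSE])
    cs <- colSums(M)
    n11 <- colSums(M[y == 1L, , drop = FALSE])
    n10 <- cs - n11
    n1 <- sum(y)
    n01 <- n1 - n11
    n00 <- (nrow(M) - n1) - n10
    mi <- .mi_2x2_vec(n11, n10, n01, n00)
    informative <- cs > 0 & cs < nrow(M)
    bin_res <- data.table(feature_id = bin_ids, mi_nats = mi,
                          informative = informative, n_used = nrow(M),
                          estimator = "plugin_discrete")
  }

  other <- meta[value_type != "binary"]
  oth_res <- if (nrow(other)) rbindlist(lapply(seq_len(nrow(other)), function(i) {
    fid <- other$feature_id[i]
    v <- columns[[fid]]
    ok <- !is.na(v)
    vv <- v[ok]
    yy <- y[ok]
    n_lv <- length(unique(vv))
    if (length(vv) == 0L || n_lv <= 1L) {
      return(data.table(feature_id = fid, mi_nats = NA_real_,
                        informative = FALSE, n_used = length(vv),
                        estimator = "none"))
    }
    discrete <- other$value_type[i] == "count" &&
      n_lv <= count_discrete_max_levels
    if (discrete) {
      data.table(feature_id = fid, mi_nats = plugin_mi(vv, yy),
                 informative = TRUE, n_used = length(vv),
                 estimator = "plugin_discrete")
    } else {
      est <- knn_mixed_mi(vv, yy, k = k, n_runs = n_runs,
                          seed = if (is.null(seed)) NULL else seed + i * 1000L)
      data.table(feature_id = fid, mi_nats = est$mi,
                 informative = !is.na(est$mi), n_used = est$n,
                 estimator = "knn_mixed")
    }
  })) else NULL

  res <- rbindlist(Filter(Negate(is.null), list(bin_res, oth_res)))
  res <- merge(res, meta[, .(feature_id, value_type, set_type)],
               by = "feature_id", sort = FALSE)
  n_noninf <- res[informative == FALSE & estimator != "knn_mixed", .N]
  n_skipped <- res[informative == FALSE & estimator == "knn_mixed", .N]
  ranked <- res[informative == TRUE]
  ranked[, mi_scaled_pct := 100 * mi_nats / h_case]
  setorder(ranked, -mi_scaled_pct, feature_id)
  ranked[, rank := seq_len(.N)]
  out <- ranked[, .(feature_id, set_type, value_type, estimator, n_used,
                    mi_nats, mi_scaled_pct, rank)]
  setattr(out, "caseness_entropy_nats", h_case)
  setattr(out, "n_non_informative", n_noninf)
  setattr(out, "n_skipped", n_skipped)
  setattr(out, "class", c("ranked_feature_sets", class(out)))
  out[]
}
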