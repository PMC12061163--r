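# Independent oracle implementations used across the test suite. These are
# deliberately naive (loops, enumeration, direct formulas) and share no code
# with the package internals.

# closed-form probability that a simulated patient meets the observed
# caseness definition, derived from the generative model's product
# structure: eligibility x (latent mixture of coding x medication) x no
# exclusion. Independent of the simulator code path.
oracle_caseness_probability <- function(cfg) {
  ages <- seq(cfg$age_range[1], cfg$age_range[2])
  p_age <- mean(ages >= 18 & ages <= 70)
  a <- cfg$registration_years_range[1]
  b <- cfg$registration_years_range[2]
  thr <- 364.5 / 365.25  # round(u * 365.25) >= 365
  p_reg <- if (b <= a) as.numeric(a >= thr) else
    (b - max(a, min(thr, b))) / (b - a)
  p_lat <- cfg$coding_probability * cfg$medication_probability_case
  p_ctl <- cfg$background_inclusion_probability *
    cfg$medication_probability_control
  p_age * p_reg * (1 - cfg$exclusion_probability) *
    (cfg$true_prevalence * p_lat + (1 - cfg$true_prevalence) * p_ctl)
}

# brute-force reachability in a code DAG by path enumeration
oracle_closure <- function(edges, roots) {
  reach <- unique(roots)
  repeat {
    nxt <- unique(c(reach, edges$child[edges$parent %in% reach]))
    if (length(nxt) == length(reach)) return(sort(nxt))
    reach <- nxt
  }
}

# per-patient re-evaluation of the study-population / caseness predicate,
# written directly from the stated definition
oracle_labels_one <- function(pat, dx, rx, index, med_names) {
  age <- floor(as.numeric(index - as.Date(paste0(pat$birth_year, "-07-01"))) /
                 365.25)
  reg_ok <- as.numeric(index - pat$registration_date) >= 365
  win <- index - 3652  # exclusive lower bound of the 10-year window
  inc <- c("INC_PD", "INC_BPD", "INC_DYS", "INC_PDD", "INC_CHRDEP",
           "INC_CPTSD", "INC_CHRPTSD")
  exc <- c("EXC_BIP", "EXC_SCZ", "EXC_DEM")
  md <- c(inc, exc[1:2],
          grep("^PSY_|^MD", unique(dx$code), value = TRUE))
  dx_p <- dx[dx$patient_id == pat$patient_id & dx$date <= index, ]
  rx_p <- rx[rx$patient_id == pat$patient_id & rx$date <= index &
               rx$date > win, ]
  has_inc <- any(dx_p$code %in% inc)
  has_exc <- any(dx_p$code %in% exc)
  has_md_recent <- any(dx_p$code %in% md & dx_p$date > win)
  med_hit <- FALSE
  for (m in med_names) {
    med_hit <- med_hit | any(grepl(tolower(m), tolower(rx_p$name),
                                   fixed = TRUE))
  }
  eligible <- age >= 18 & age <= 70 & reg_ok
  in_pop <- eligible & (has_md_recent | med_hit) & !has_exc
  list(in_pop = in_pop, is_case = in_pop & has_inc & med_hit & !has_exc)
}

# O(n^2) sample entropy by direct template matching
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  if (nt < 2) return(NA_real_)
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# spectral entropy by direct DFT sums
oracle_spectral <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  nb <- n %/% 2
  pw <- numeric(nb)
  for (f in 1:nb) {
    re <- sum(z * cos(-2 * pi * f * (0:(n - 1)) / n))
    im <- sum(z * sin(-2 * pi * f * (0:(n - 1)) / n))
    pw[f] <- re^2 + im^2
  }
  if (sum(pw) <= 0) return(NA_real_)
  p <- pw / sum(pw)
  p <- p[p > 0]
  -sum(p * log(p)) / log(nb)
}

# quarterly entropy by explicit per-year computation
oracle_quarterly <- function(dna, year, month) {
  ys <- unique(year)
  vals <- c()
  for (y in ys) {
    sel <- year == y
    if (length(unique(month[sel])) != 12) next
    q <- c(sum(dna[sel & month <= 3]),
           sum(dna[sel & month >= 4 & month <= 6]),
           sum(dna[sel & month >= 7 & month <= 9]),
           sum(dna[sel & month >= 10]))
    if (sum(q) == 0) {
      vals <- c(vals, 0)
    } else {
      p <- q / sum(q)
      p <- p[p > 0]
      vals <- c(vals, -sum(p * log(p)) / log(4))
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# active information by explicit window enumeration and the plug-in MI
# formula applied to the pattern/next frequency table
oracle_active_info <- function(x, history = 12, recent = 3) {
  x <- as.integer(x != 0)
  need <- history + recent
  if (length(x) < need) return(NA_real_)
  x <- tail(x, need)
  pats <- character(0)
  nxts <- integer(0)
  for (p in 1:history) {
    pats <- c(pats, paste(x[p:(p + recent - 1)], collapse = ""))
    nxts <- c(nxts, x[p + recent])
  }
  tab <- table(pats, nxts)
  p <- tab / sum(tab)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) {
      mi <- mi + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
    }
  }
  mi
}

# direct plug-in MI formula for a 2x2 joint count table
oracle_mi_2x2 <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  cells <- c(n11, n10, n01, n00)
  rows <- c(n11 + n10, n11 + n10, n01 + n00, n01 + n00)
  colsum <- c(n11 + n01, n10 + n00, n11 + n01, n10 + n00)
  mi <- 0
  for (i in 1:4) {
    if (cells[i] > 0) {
      mi <- mi + cells[i] / n * log(cells[i] * n / (rows[i] * colsum[i]))
    }
  }
  mi
}

# true MI between a two-class label (p = 0.5) and a Gaussian mixture
# observation, by one-dimensional numerical integration
oracle_gaussian_mixture_mi <- function(mu0 = 0, mu1 = 3, sd = 1) {
  f <- function(t) 0.5 * dnorm(t, mu0, sd) + 0.5 * dnorm(t, mu1, sd)
  hx <- integrate(function(t) {
    ft <- f(t)
    ifelse(ft > 0, -ft * log(ft), 0)
  }, mu0 - 10 * sd, mu1 + 10 * sd, rel.tol = 1e-10)$value
  hx - 0.5 * log(2 * pi * exp(1) * sd^2)
}

# brute-force regime grouping for aborted-regime counting
oracle_aborted <- function(dates_by_med, index, gap = 90, min_dur = 84) {
  total <- 0
  index <- as.numeric(as.Date(index))
  for (dates in dates_by_med) {
    dates <- sort(as.numeric(as.Date(dates)))
    if (!length(dates)) next
    groups <- list()
    cur <- dates[1]
    for (d in dates[-1]) {
      if (d - cur[length(cur)] > gap) {
        groups[[length(groups) + 1]] <- cur
        cur <- d
      } else cur <- c(cur, d)
    }
    groups[[length(groups) + 1]] <- cur
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      span <- max(g) - min(g)
      open_last <- gi == length(groups) && (index - max(g)) <= gap
      if (span < min_dur && !open_last) total <- total + 1
    }
  }
  total
}

# a tiny hand-built cohort for deterministic phenotype/feature tests
tiny_cohort <- function() {
  idx <- as.Date("2021-12-31")
  patients <- data.table::data.table(
    patient_id = sprintf("T%02d", 1:8),
    birth_year = c(1980, 2004, 1975, 1960, 1990, 1985, 1970, 1995),
    registration_date = as.Date(c("2010-01-01", "2012-05-01", "2021-10-01",
                                  "2008-03-01", "2015-06-01", "2009-01-01",
                                  "2005-01-01", "2014-01-01"))
  )
  diagnoses <- data.table::data.table(
    patient_id = c("T01", "T02", "T03", "T04", "T04", "T05", "T06", "T07",
                   "T07"),
    code = c("INC_PD", "INC_PD", "INC_DYS", "INC_BPD", "EXC_SCZ", "PSY_GAD",
             "INC_CHRDEP", "PSY_DEP", "PSY_DEP"),
    date = as.Date(c("2015-06-01", "2018-01-01", "2021-11-01", "2015-01-01",
                     "2016-01-01", "2020-02-01", "2009-06-01", "2018-01-01",
                     "2019-05-01"))
  )
  prescriptions <- data.table::data.table(
    patient_id = c("T01", "T02", "T03", "T04", "T05", "T06", "T07"),
    name = c("Sertraline 50mg tablets", "Fluoxetine", "Citalopram",
             "Olanzapine", "Diazepam", "Mirtazapine", "Venlafaxine"),
    class = c("antidepressant", "antidepressant", "antidepressant",
              "antipsychotic", "hypnotic_anxiolytic", "antidepressant",
              "antidepressant"),
    date = as.Date(c("2020-03-01", "2019-08-01", "2021-11-15", "2017-02-01",
                     "2021-01-10", "2010-06-01", "2020-09-01"))
  )
  appointments <- data.table::data.table(
    patient_id = rep("T01", 12),
    date = seq(as.Date("2021-01-15"), by = "month", length.out = 12),
    status = rep("attended", 12)
  )
  truth <- data.table::data.table(patient_id = patients$patient_id,
                                  latent_status = FALSE)
  structure(list(patients = patients, diagnoses = diagnoses,
                 prescriptions = prescriptions, appointments = appointments,
                 referrals = data.table::data.table(
                   patient_id = character(), type = character(),
                   date = as.Date(character())),
                 truth = truth, config = NULL),
            class = "mh_cohort")
}
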