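---
title: "Screening primary-care records for complex mental health difficulties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening primary-care records for complex mental health difficulties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Complex mental health difficulties (CMHD) — persistent, disruptive
mental-health problems short of severe mental illness, overlapping
personality disorder, dysthymia and complex PTSD — are heavily under-coded
in primary-care electronic health records. Population surveys put the
prevalence at roughly 3–5% of adults, while records-based definitions
identify an order of magnitude fewer. A records-based *caseness* definition
therefore captures only the recognised tip of the condition, and most true
cases sit unlabelled among the controls.

`mhscreen` implements an information-theoretic screen for record features
associated with such a caseness definition: rather than fitting a
classifier, it ranks a large census of *feature sets* — single record
attributes, thematic feature families, and wildcard combinations of family
levels — by their two-way mutual information (MI) with caseness, scaled to
the entropy of the caseness variable. MI makes few assumptions (no
directionality, linearity, or residual distribution) and behaves sensibly
when the outcome is rare, where variance-explained measures struggle.

## The caseness phenotype

A patient is in the **study population** if they are aged 18–70 inclusive
at the index date, registered with their practice for at least one year,
have either a mental-disorder code or a medication of interest within the
ten-year lookback window, and have no exclusion diagnosis
(schizophrenia/bipolar-disorder/dementia analogues). Within the study
population, a **case** has

1. at least one inclusion-list diagnosis (personality disorder, dysthymia,
   chronic depression, persistent depressive disorder, complex/chronic
   PTSD analogues) at *any* time up to the index date, and
2. a prescription for a medication of interest within the ten years before
   the index date.

Everyone else in the study population is a control. Diagnosis lists are
expanded through the code hierarchy (`code_closure()`): a parent code
subsumes all descendants. Medication matching is case-insensitive substring
search on the product name, since prescription tables carry free-text
product names.

Numerical conventions, all configurable in `phenotype_spec()`:

* **Date windows are half-open** `(index − 10y, index]`: an event exactly
  ten years before the index date is outside the window. "Within ten years
  prior" is read as a strict lookback.
* **Age** is completed years at the index date computed from the birth
  year with a mid-year (1 July) birthday convention, because the
  anonymised records keep only the birth year.
* Patients with missing demographics are excluded with a logged count
  rather than guessed at.

## The synthetic cohort

The real data behind this kind of screen (linked primary-care records of
about a million people) cannot be shipped, so `generate_cohort()` simulates
event streams with a *planted* latent complexity status, and every
downstream stage is tested against that ground truth. The generator's
defaults are the study conditions:

* latent prevalence 4% (the survey range is 3–5%);
* `coding_probability = 0.10`: only one latent case in ten carries a coded
  inclusion diagnosis, emulating roughly ten-fold under-coding, so
  observed caseness lands near 0.3% of the total population and near 2% of
  the study population — which puts the caseness entropy near 0.1 nats,
  the regime the scaled-MI ranking is designed for;
* the count of distinct generic psychiatric codes is negative binomial
  (over-dispersion is typical of EHR code counts), with the mean
  multiplied by 4 for latent cases — the planted dose-dependent
  association — and further multiplied by 2.5 for patients whose inclusion
  diagnosis is actually coded. This coding-propensity coupling reflects
  that recognition and richness of psychiatric coding travel together, and
  it is what makes the observed (coded) cases show a monotone dose
  dependence on the diagnosis count, with that count the single
  outstanding feature of the screen — the qualitative structure the method
  is meant to recover;
* antipsychotic prescribing is elevated in latent cases on the odds scale
  (×5), the analogue of antipsychotics being used for mood stabilisation
  outside psychotic illness;
* appointments follow a monthly Poisson process; each appointment is
  missed (DNA) with a logistic probability shifted for latent cases and
  with noisier month-to-month variation (×3 on the logit noise SD), so
  cases have more, and more erratic, non-attendance.

The latent status is written to a separate truth file and never appears in
the analysis-facing tables, mimicking a blinded analysis. With perfect
coding (`coding_probability = 1`, medication probability 1 for cases and 0
for controls, no background inclusion coding or exclusion codes), observed
caseness equals latent status exactly on the eligible population — a
property the test suite checks, along with agreement of the observed
caseness rate with the closed-form probability implied by the generative
model's product structure.

What the generator does **not** emulate: realistic terminology content
(the vocabulary is a miniature stand-in of ~70 codes), seasonality and
secular trends, correlated comorbidity structure, practice-level coding
variation, or informative registration/deregistration. Tests passing on
this cohort show that the pipeline recovers what was planted under these
idealised conditions; they do not certify performance on real records.

## Component features

Features are any record attribute that is not itself the caseness
definition; inclusion/exclusion diagnosis codes are therefore not
features, but medication-of-interest presence is (prescriptions are only
half of the definition). Each feature belongs to exactly one of eight
families: Antecedent, Concurrent, ServiceUse, Treatment, Inconsistency,
PatternsOfPrescription, RelevantPrescriptions, AntipsychoticPrescription;
each carries a provenance tag (`fs_literature`, `fs_interviews`,
`fs_clinician`) indicating the kind of source such a feature list is
compiled from.

The temporal features of non-attendance deserve their definitions spelled
out, since "entropy of non-attendance" admits many reconstructions. All
operate on the monthly attendance series of the last five years (calendar
month bins from `max(registration, index − 5y)` to the index date), and
all logarithms are in nats:

* **Average quarterly entropy**: for each full calendar year, the four
  quarterly DNA counts are normalised to proportions; Shannon entropy is
  divided by `ln 4` so each year scores in [0, 1] (a year with no DNA
  scores 0); the feature is the mean over full years. 0 = all
  non-attendance concentrated in one quarter; 1 = uniform.
* **Spectral entropy**: Shannon entropy of the normalised power spectrum
  (positive frequencies of the mean-centred monthly DNA count series),
  divided by the log of the number of spectral bins. A single dominant
  periodicity gives ~0; white-noise-like non-attendance gives ~1. Constant
  series have zero power and return `NA`.
* **Sample entropy** of the monthly appointment-count series: the standard
  −ln(A/B) template-matching statistic with embedding `m = 2` and
  tolerance `r = 0.2 × SD` (Chebyshev distance, self-matches excluded).
  For a constant series the default tolerance collapses to zero and the
  value is `NA`; with an explicit positive tolerance a constant series
  scores 0 (perfect regularity).
* **Active information**: binarise months (any DNA = 1); over the final 15
  months, the plug-in MI between each 3-month history pattern and the
  following month's indicator, across the 12 sliding windows whose history
  lies in the preceding year. It measures how consistent the latest
  non-attendance is with its own recent past.

The `m`, `r`, and window constants have no field-standard values for this
setting; they are package defaults, stated in `feature_params()` and
overridable. The per-patient sample-entropy kernel is implemented in C++
because it is quadratic in the series length and runs once per patient.

## Families, levels, combinations

Each family is summarised per patient by its *component count* — how many
of its member features are present (binary feature = 1; count feature
> 0; continuous feature observed and > 0) — and expanded into five level
indicators: `None` (count 0), `NotNone` (≥ 1), and `Few`/`Some`/`Many`
partitioning the positive counts at family-specific cutpoints. Where the
original analysis chose its quantiles by clinical judgement, this package
substitutes a reproducible default — tertiles of the observed positive
counts, computed once over all patients before any level is assigned — and
accepts explicit cutpoints. All five indicators are emitted as rankable
feature sets (presence and graded levels of the same family are distinct,
interpretable hypotheses).

*Combinations* constrain some families to a level and leave the rest
wildcard (`x`); a record satisfies the combination iff every constrained
indicator is true. The census is enumerated in a fixed lexicographic order
(last family varies fastest, wildcard first), so single-family constraints
and low-order interactions come first and a capped enumeration is
reproducible without any seed. Columns that are constant across patients
(non-informative) or duplicate an already-emitted column (exact equality;
the first-seen representative is kept) are pruned, and enumeration stops
at the cap — 1,000 combinations by default, which together with the ~74
component features and 40 family levels gives a census comfortably above
500 rankable feature sets. With pruning disabled, exceeding the cap is an
explicit overflow error rather than silent truncation.

## Ranking by scaled mutual information

Every informative feature set is ranked by its MI with caseness, divided
by the entropy of the caseness variable (so 100% means the feature
determines caseness and vice versa) and reported as a percentage.

* **Discrete feature sets** (binary columns, and count features with at
  most 30 distinct values) use the deterministic plug-in estimator on the
  empirical joint table. Plug-in MI is invariant to relabelling and can
  never exceed the caseness entropy.
* **Continuous feature sets** (and counts with more than 30 levels — the
  30 is a package choice, configurable) use the k-nearest-neighbour mixed
  discrete–continuous estimator in its digamma form:
  ψ(N) − ⟨ψ(N_class)⟩ + ψ(k) − ⟨ψ(m_i)⟩, with m_i the number of
  all-sample neighbours strictly within the distance of the k-th
  same-class neighbour (the point itself included), the convention of the
  field's standard implementation. Default `k = 3`. Ties are broken by a
  tiny symmetric jitter (relative scale 1e−10 of the IQR), which makes the
  estimator stochastic; the reported value is the arithmetic mean of 20
  runs, with per-run values retained so the run-to-run spread can be
  inspected. Negative means (an estimator artefact near independence) are
  clamped to 0 before scaling; raw values are kept. Classes with ≤ k
  members make the estimator undefined and the feature is flagged and
  skipped rather than guessed.

Missing feature values (e.g. entropy features of patients with no
appointments) are dropped pairwise before estimation; the scaling
denominator is always the caseness entropy of the full study population.
Ranks are 1 = best, ties broken lexicographically by feature id so the
full ranking is byte-reproducible under a fixed master seed (the pipeline
fans the master seed out to fixed per-stage and per-feature sub-seeds).

## Evaluation and disclosure control

For binary feature sets the pipeline tabulates the 2×2 coincidence of
feature and caseness and reports prevalence per 1,000, class balance
accuracy (CBA), odds ratio, PPV and NPV. CBA —
½·[TP/min(TP+FN, TP+FP) + TN/min(TN+FP, TN+FN)] — is preferred over raw
accuracy for rare, weakly separable outcomes. Prevalence is implemented as
×1,000 (a feature present in most records scores ~850 per 1,000); the
odds ratio with an empty FP or FN cell is reported as infinite
(unavailable-with-direction) unless the Haldane +0.5 correction is
requested. Odds ratios are estimated in the context of all unmeasured
confounding: the screen deliberately does not adjust for confounding or
collider structure, which would require a causal model this exploratory
method does not assume.

Published counts pass through statistical disclosure control **before any
statistic is computed from them**: counts ≤ 7 are suppressed, the rest
rounded to the nearest ten (half-up, a documented choice where the rule is
silent on half cases), so every published count is a multiple of ten and
at least ten. Any statistic needing a suppressed cell is reported
unavailable, never imputed. The evaluation table carries both raw and
controlled statistics, labelled, with the controlled set as the
publishable one.

## Problem sizes and runtime

The default study conditions simulate 50,000 patients, of whom roughly
15–17% enter the study population, and rank ~1,100 feature sets in about
20 seconds. The test suite exercises the closed-form caseness check at
n = 50,000, the estimator benchmarks at n = 2,000–5,000, the brute-force
entropy oracles at 200 random short series per feature, and the
planted-association recovery across 20 seeded replicates of the default
cohort; these sizes were chosen so the whole suite runs in minutes while
keeping Monte-Carlo bounds tight.

## Known limitations

* The vocabulary, code lists and all generator distributions are synthetic
  stand-ins; absolute MI values from the synthetic cohort are not
  estimates of any real-world quantity — only the relative structure
  (which kinds of feature rank where) is meaningful.
* The k-NN MI estimator is biased near independence and noisy for heavily
  tied counts; the 20-run mean tames but does not remove this. Count
  features near the 30-level threshold can move between estimators with
  the data.
* Caseness reported as a fraction of the study population depends on
  filters applied upstream; the package reports the exact fraction it
  computes and does not attempt to reconcile alternative figures.
* No multiple-testing control or confounder adjustment is applied, by
  design: ranks are screening prompts, not effect estimates.
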