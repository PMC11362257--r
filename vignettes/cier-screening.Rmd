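---
title: "Screening careless survey respondents: model, predictors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening careless survey respondents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cierscreen)
```

## The problem and the model

Web panels contain a substantial fraction of careless /
insufficient-effort responders (C/IERs): respondents who answer without
processing item content. Directed questions ("select category 2") flag
them reliably but must be planted at questionnaire design time.
`cierscreen` treats detection as supervised learning: on surveys that
*did* carry directed questions (DQS), the binary outcome "missed at
least one directed question" is observable, and a tree ensemble can be
trained to predict it from content-free response features. Applied to a
new survey, the model outputs an inattentive response probability (IRP)
per respondent; thresholding the IRP (default 0.5, inclusive) yields the
flag, and moving the threshold sets the screening severity.

Tree ensembles — a random forest and gradient-boosted trees — are used
because they dominate deep alternatives at the training sizes this
problem offers (thousands, not tens of thousands, of balanced rows).

## The thirteen predictors

All per-respondent features come from a block of 12 *consecutive* Likert
items plus the total response time; two survey-level features describe
the questionnaire itself. The block should mix reverse-worded items or
items from different constructs — otherwise an attentive respondent can
legitimately straightline it; the `block_heterogeneous` config flag
records (but cannot verify) that property.

**Sequence indices.** `ls` is the longest run of identical consecutive
responses; `r2c` / `r3c` flag use of at most two / three distinct
categories; `ac` counts transitions between adjacent categories
(|difference| = 1) and `mac` is the longest unbroken chain of them.
Together they catch straightlining and the near-straightlining patterns
(e.g. 2,2,2,3,3,2,2 or alternating 4,5,4,5) that a run length alone
misses. Intra-individual response variability (the within-row standard
deviation) is deliberately *not* used: being an SD, it does not adjust
cleanly for the number of categories, while `r2c`/`r3c`/`ac`/`mac`
jointly cover the same behavior and normalize trivially.

**Outlier indices.** `maha` is the squared Mahalanobis distance
(x − x̄)′Σ⁻¹(x − x̄) of the respondent's 12-item vector; `maha_p` its
upper-tail χ²(12) probability, i.e. the p-value for "this respondent
does not deviate from the mean vector". `maha2` / `maha2_p` repeat this
on the two most highly correlated items (χ²(2)): a pair so strongly
coupled that an inconsistent answer on just those two is itself a
careless signal. `absdevi` is the covariance-free L1 deviation from the
mean vector. The reference moments x̄, Σ are estimated *excluding* rows
with `ls = 12`, because straightliners shift the mean toward their
category and deflate the covariance.

**Paradata.** `time` is the total response time capped at the Tukey
upper fence and divided by the questionnaire length (seconds per item);
`time_m` the survey median of capped totals (kept in raw seconds — its
purpose is exactly to encode between-survey pacing differences); and
`nitems` the questionnaire length (longer questionnaires breed more
careless responding).

**Normalization.** To pool surveys with different layouts:
`ls/12`, `K·ac/12`, `K·mac/12`, `maha/12²`, `absdevi/(12·K)`; the
binary flags, the p-values (already on a common scale) and the
fixed-dimension `maha2` pass through. The block length is a parameter
(`n_block_items`, default 12) and all normalizations use it, so the
method ports to other block sizes.

## Numerical choices and degenerate inputs

* **Singular covariance.** With few categories or small reference
  samples Σ can be rank-deficient. A ridge ε·mean(diag(Σ))·I is added
  with ε = 10⁻⁶, escalating tenfold to 10⁻³ before erroring; each
  application is reported. The distance stays on the squared scale
  throughout so the χ² p-value is coherent.
* **Moment fallback.** If excluding straightliners leaves fewer than
  `ncol + 2` rows (the minimum for a non-degenerate covariance), the
  moments fall back to all rows and the event is flagged
  (`excluded_all_flag`) with a warning.
* **Correlation pick.** "Most highly correlated pair" is read as maximum
  *signed* Pearson correlation, computed on the same straightliner-
  filtered rows as the moments (the exclusion is specified for the
  moments; applying it to the pair keeps the two consistent). With
  reverse-worded items in the block the strongest association may be
  negative; `pair_by_abs_correlation = TRUE` switches to |r|. Ties
  resolve to the lexicographically smallest pair.
* **Time capping.** "Extreme of the upper whisker" is implemented as the
  fence Q3 + 1.5·IQR itself (not the largest observation below it),
  with type-7 (linear interpolation) quartiles; both the multiplier and
  the quartile type are arguments. Values above the fence are read as
  interrupted sessions, not slow responding. `time_m` is the median of
  the *capped* totals. Capping is per survey — and per device group
  when PC and smartphone respondents are modeled separately, since
  their time distributions differ; device filtering happens before
  feature computation.
* **Thresholding** is inclusive (IRP exactly at the threshold flags the
  respondent).

## Detector defaults

The tuning protocol fixes *what* is tuned: the forest's
split-candidate count `mtry` by out-of-bag misclassification error, the
boosting depth by stratified tenfold cross-validated log-loss, ties to
the simpler model. The remaining knobs are package defaults, documented
rather than inferred: 500 trees per forest with an `mtry` grid of
1..13; boosting learning rate 0.1 with the round count set by early
stopping on the CV folds (patience 20, cap 500). Every stochastic
operation takes an explicit seed, and refitting with the same data and
seed reproduces predictions exactly.

## Evaluation harness

Training never uses raw pooling: each training survey contributes m
randomly drawn careless and m attentive respondents, where m is the
minimum careless count among the training surveys, giving exactly 50%
prevalence (2·m·S rows over S surveys). Surveys that cannot supply m
are dropped with a warning. In leave-one-survey-out evaluation the
balancing count is, by default, recomputed within each fold from the
training surveys only — computing it once globally (also supported,
`m_mode = "global"`) would leak the held-out survey's careless count
into training-set construction, which matters in principle even though
it changes little in practice. Held-out surveys are scored *in full*,
not balanced.

Two aggregates are reported: Mean 1 averages the per-survey metric
values (undefined cells — e.g. precision with no predicted positives —
are NaN, excluded from the average, and counted in an `n_excluded`
attribute, never silently zeroed); Mean 2 recomputes the metrics on the
pooled predictions, so its confusion counts are the sums of the
per-survey counts. To compare settings with different careless rates,
`set_prevalence()` downsamples positives (attentive rows untouched)
until the target rate holds, averaging over 20 resamples by default
(the repetition count is a package choice; a single resample is noisy
at low target rates). Recall is invariant in expectation under this
operation; precision is not — which is the point of reporting it.

## What the synthetic generator emulates — and what it does not

`simulate_study()` stands in for multi-survey field data. Its defaults
are fixed to the regime the method targets: six surveys of 400
respondents; 5–10 response categories; questionnaire lengths 60–150
items; attentive pacing around 6 s/item with log-normal spread (σ =
0.4); careless rates rising from 0.25 to 0.5 across surveys — the band
observed in unscreened web panels. Attentive respondents follow a
one-factor graded model per ~12-item construct (loading 0.75, four
reverse-keyed items per construct) discretized through equal-probability
normal thresholds, with the middle category widened by 0.3 latent SD to
mimic the middle-category tendency documented for Japanese and other
Asian panels; they slip on a directed question with probability 0.01.
Careless respondents draw one of four behaviors (uniform random 0.40,
straightlining 0.30, adjacent-category drift 0.15, fast random 0.15)
applied to the *whole* questionnaire, directed questions included — so
DQS failure is a consequence of behavior, never copied from the truth
label — and fast responders' times are multiplied by 0.35.

These defaults were chosen once, as a description of realistic study
conditions, and the acceptance checks run against them as-is.

Deliberately not modeled: per-page or per-item timing, smartphone
screen-operation paradata (scroll speed, text deletions), partially
careless respondents who lapse midway through a questionnaire,
content-dependent response styles, and item nonresponse. Passing tests
on this generator therefore show that the pipeline recovers the careless
behaviors it encodes under realistic noise — not that field accuracy on
any particular panel will match.

A note on reproducibility granularity: each survey gets its own seed
derived from the study seed, so surveys are independently reproducible,
but appending respondents to a survey redraws that survey (base R's
generator has no per-respondent substreams).

## Problem sizes used in the shipped checks

The test suite exercises the exhaustive sequence-index oracle on all
5⁶ length-6 sequences; Mahalanobis calibration on 5 000 multivariate
normal rows (Kolmogorov–Smirnov at α = 0.01); null-safety of the LOSO
harness on four label-permuted surveys of 200 respondents; and signal
recovery on the default six-survey study with full `mtry` tuning.
Balancing arithmetic is checked at the published survey sizes (minimum
careless counts 187 and 196 giving pooled training sizes 5 610 and
4 704, and the hypothetical 162-count variant giving 3 564).

## Known limitations

* The DQS outcome is a *proxy* for carelessness: a respondent can miss a
  directed question once yet answer everything else attentively, and a
  lucky straightliner can pass both. The detector inherits this label
  noise.
* A single K is assumed within the 12-item block; blocks mixing scale
  widths need recoding before use.
* Respondents are screened on one block; choosing a different block in
  the same survey can change individual IRPs (position effects are real
  and are why two near-identical surveys may disagree).
* No model trained on real panel data ships with the package; users
  train on their own DQS-bearing surveys or on synthetic studies.
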