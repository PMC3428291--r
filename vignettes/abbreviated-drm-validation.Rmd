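---
title: "Methods: scoring and validating the abbreviated Day Reconstruction Method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating the abbreviated Day Reconstruction Method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmvalidate)
```

This vignette documents the models, conventions, and numerical choices
behind `drmvalidate`.  It is the package's reference for *why* each
statistic is computed the way it is; the README shows *how* to run it.

## The instrument and the scoring model

A Day Reconstruction Method (DRM) interview yields a sequence of
episodes, each with a half-open time interval `[start, end)` in
minutes since midnight, one or more activity codes from a fixed
22-entry catalog (`drm_activities()`), companion codes, and seven
affect items rated 1–3.  Abbreviated forms randomize respondents to
four sets: A, B, C reconstruct only the morning, afternoon, or evening
episode by episode; set D records the whole day as three
coarse segments (morning / afternoon / evening) with one affect block
each and *no durations*.  The validation design administers a short
set at baseline ("test") and the full-day instrument one week later
("retest").

Scoring, per respondent-wave:

* positive affect `PA` = mean of calm/relaxed and enjoyment;
* negative affect `NA` = mean of the five negative items;
* net affect = `PA − NA`, with attainable range exactly `[−2, 2]`
  (both endpoints are reached on the 3^7 rating grid; the test suite
  enumerates it);
* for episode-based sets, all three are weighted by episode duration,
  and the **U-index** is the share of reported minutes in episodes
  whose highest-rated feeling is a negative item;
* for set D, raw (unweighted) means are taken and the U-index is not
  defined.

Conventions, each centralized so the alternative is one argument away:

* **Unpleasantness tie rule.**  An episode counts as unpleasant only
  when the maximum negative rating *strictly* exceeds the maximum
  positive rating — the defining phrase is that the top feeling *is* a
  negative one, which a tie does not satisfy.
  `episode_is_unpleasant(ties_unpleasant = TRUE)` flips the rule.
* **Incomplete episodes.**  An episode missing any of the seven items
  is excluded from scoring with a warning and a per-wave exclusion
  count; no imputation is attempted.
* **Period boundaries.**  Morning runs from wake-up to 12:00,
  afternoon 12:00–18:00, evening from 18:00 onward.  When the full-day
  record is sliced to match a short set (`slice_full_wave`), episodes
  straddling a boundary are split there with durations prorated and
  ratings carried unchanged; since boundaries and episode times are
  integer minutes, proration is exact and conserves total time.  How
  the original analysis allocated straddling episodes is not
  documented anywhere we know of; this is a declared convention, not
  an inference.
* **Intervals.**  Durations are integer minutes on half-open
  intervals, so abutting episodes never double-count a minute.

## Reliability statistics

**ICC.**  Test–retest reliability uses the one-way random-effects,
single-measure intraclass correlation: with two interchangeable
measurements per subject, `ICC = (MSB − MSW) / (MSB + MSW)` from the
one-way ANOVA decomposition.  A two-way model would ascribe a fixed
wave effect; the one-way form matches the subject-variance /
measurement-error reading of reliability and needs no rater term.  The
95% CI comes from the F pivot: `F0 = MSB/MSW`,
`FL = F0 / qf(0.975, n−1, n)`, `FU = F0 · qf(0.975, n, n−1)`, each
mapped through `(F − 1)/(F + 1)`.  Negative estimates (within-subject
scatter exceeding between-subject scatter) are reported as computed
but banded "poor", since the coefficient's floor is theoretically
zero.  Landis–Koch bands are right-closed on 0.2-wide intervals, so
0.4 is still "fair".

**Paired comparisons.**  Mean change between waves uses the paired t
test with Cohen's d corrected for paired designs,
`d = t · sqrt(2(1 − r)/n)` with `r` the test–retest correlation; in
large surveys trivial shifts reach significance, so the effect size is
displayed only for significant tests (it is always stored).  On
exactly identical waves the paired t is 0/0 and the function errors
rather than fabricating `t = 0`.

**Correlations.**  Pearson CIs use the Fisher z transform with
standard error `1/sqrt(n − 3)`; Spearman is the Pearson correlation of
average ranks.  Between-set descriptive tests report Cramér's V
(chi-square), Cohen's f (ANOVA), and Hedges' g (two groups).

## Agreement for the supplementary questions

Each interview ends with 14 yes/no questions about the previous day
("Did you feel worried for much of the day?") and two 3-point
comparison questions (mood / anxiety relative to peers).

* **Delta (2×2).**  The Delta model treats each (test, retest) answer
  pair as either a *genuine recognition* — both answers agree on
  category *i*, with probability `delta_i` — or a random guess.  The
  published variants leave the 2×2 case over-parameterized (any
  guessing distribution can be traded against the `delta_i`), so this
  package pins the model by making guesses uniform over the four
  cells.  That yields an identifiable two-parameter model whose
  maximum-likelihood fit has a closed form
  (`delta_i = x_ii/n − (x_12 + x_21)/(2n)`, overall
  `Delta = delta_1 + delta_2`); we use the closed form rather than a
  numerical multi-start because the two provably coincide, and the
  test suite re-derives the optimum with an independent nested
  grid search over the likelihood surface.  The model forces the two
  discordant cells to be equal, giving a 1-df chi-square goodness-of-fit
  test; its p-values are calibrated (checked by Monte Carlo).
  Estimates below zero mean worse-than-chance agreement, where the
  guessing interpretation no longer applies.  On balanced margins
  Delta coincides with kappa; under strong marginal imbalance kappa
  collapses and Delta does not, which is the reason to report both.
* **Kappa.**  The 3-point items use weighted kappa with linear
  disagreement weights `|i − j|/(K − 1)` by default — the categories
  ("better / same / worse") look equidistant, and the scheme is
  recorded in the output with a quadratic option available.

## Criterion validity with a continuous gold standard

Classical ROC analysis needs a binary gold standard; here the gold
standard (the full-day score) is continuous.  The nonparametric
estimator scores every subject pair with distinct gold values 1 if the
short-version scores order the pair concordantly, 0.5 if they tie, 0
otherwise; the AUC is the mean pair score.  Pairs *tied on the gold
standard* are excluded from the denominator (`n_pairs_used` reports
the count): duration-weighted affect can tie exactly (e.g. both
respondents at the scale ceiling), and a tied pair carries no ordering
information.  The standard error is the delete-one jackknife over
subjects, computed in O(n²) from the precomputed kernel matrix; it
matches the U-statistic structural-components estimator up to the
exact finite-sample factor `(n−1)/(n−2)` and converges to it.  The
implementation is pinned to a brute-force pair enumeration in the
tests.

The pipeline reports two AUC families: pooled baseline sets A+B+C
(and separately set D) against the full retest, and — to remove
week-to-week affect drift — within-retest comparisons of each period
slice against the same day's full-day score.  The "global" row pools
the three period-level comparisons' pairs rather than summing the
slices (the summed slices *are* the full day, which would compare the
gold standard with itself).

## The demographic regression

Baseline net affect is regressed on education (primary completed or
more = 1), setting (urban = 1), household income (top three quintiles
= 1), sex (male = 1), and age.  The initial model adds all six
pairwise interactions among the four categorical predictors — age
stays a linear covariate — and a nested-model F test
(`[(RSS_r − RSS_f)/df1] / [RSS_f/df2]`) asks whether the interaction
block earns its variance.  Pruning is a single pass: fit the initial
model, drop every interaction not significant at the 5% level at
once, refit.  No stepwise search is performed, so p-values of the
final model are interpretable in the usual single-refit sense.
Interaction term labels are canonicalized to R's ordering so designs
round-trip through `terms()`.

## Activity profiles

For every activity reported by the analysis sample (episode-based
baseline sets with a completed retest), the profile gives the
percentage of respondents reporting it per wave and the mean net
affect experienced during it, weighting the sample by the time each
respondent spent in the activity; an episode listing several
activities contributes its full duration and affect to each (reporting
percentages can therefore exceed 100 in total).  The standard error is
the ratio-estimator form for a weighted mean over respondents.
Temporal stability is assessed only for activities reported at
baseline by at least 5% of the sample — an *inclusive* threshold
applied to the baseline percentage only — via per-activity
test–retest Pearson correlations (computed from 3 reporters, CI from
4), the Spearman correlation between the two waves' affect rankings
(average ranks, so the deterministic tie-break by activity code cannot
affect it), and the Pearson correlation of mean net affect across
activities.  Whether the historical analyses averaged over episodes or
over respondent-level aggregates is not documented; the time-weighted
contract above is the default and `respondent_level = TRUE` gives
every reporter equal weight instead.  Set-D waves are excluded: their
affect blocks are not linked to single activities.

## The synthetic cohort

The generator (`cohort_config`, `generate_study`) emulates the
validation study's design so that every statistic above can be checked
by parameter recovery: 1560 respondents by default, sets allocated
with probability 1/4 each, a full-day retest for all but a
completely-at-random 22/1560 dropout, and demographic marginals shaped
on a mixed urban/rural older adult sample (53% female, mean age 57,
44% rural, half the cohort without completed primary education).

Affect follows a latent-threshold model, the simplest mechanism that
produces correlated 1–3 ordinal items:

```
latent(episode) = mu + X beta + person + wave + activity offset + episode noise
item rating    = cut(±latent + item noise) into {1, 2, 3}
```

with independent Gaussian components (defaults: person 0.6, wave 0.45,
episode 0.5, item 0.8 on the latent scale).  Positive items load
positively, negative items negatively.  The demographic effects
default to positive sex, income, and setting coefficients with
negative education×sex and income×sex interactions (the education and
income effects are stronger for women), matching the qualitative
pattern the instrument is known to show.  Thresholds are calibrated
analytically — the demographic variance is enumerated exactly over the
16 binary-covariate cells — so that a positive item's marginal is
roughly (0.15, 0.50, 0.35) and a negative item's (0.87, 0.11, 0.02),
which lands wave-level PA near 2.2 and NA near 1.15; the cutpoints are
stored in the config, not hard-coded.  Days are built from a
per-respondent wake time (≈ 6:30 ± 45 min) and bedtime (≈ 22:30 ± 45
min); each period holds 2–4 episodes whose log-normal raw durations
are renormalized to tile the period exactly in integer minutes.
Supplementary yes/no answers are stable latent answers flipped
independently per wave with an item-specific probability — a model
with a closed-form kappa used as an oracle — and the 3-point items
move to a uniformly chosen other category with their flip probability.

What the generator does *not* emulate, hence what passing tests do not
show about field data: affect is one latent dimension, so positive and
negative items are perfectly (anti)correlated up to noise, and
genuinely unpleasant episodes are rarer than in the field (the
generated U-index runs below typical survey levels, and its
reliability is correspondingly low); there is no diurnal affect cycle,
no weekday/weekend structure, no informative dropout, and activity
choice is independent of period and demographics.  Conclusions about
estimator correctness transfer; conclusions about field-data effect
sizes do not.

## Problem sizes and calibration checks

The test suite pins every estimator to an independent oracle (ANOVA
decomposition for the ICC at 1e−12; brute-force pair enumeration for
the AUC, exact; hand RSS for the nested F; direct formulas for the
kappas; nested grid search for Delta at 1e−6) and calibrates the
interval procedures by Monte Carlo at sizes chosen to keep the whole
suite under a few minutes on one core: ICC CI coverage with 500
cohorts of 200 subjects at true ICC 0.5 (coverage within 95% ± 3);
AUC under independence with 200 replicates of 500 subjects (mean
within 0.5 ± 0.02, mean jackknife SE within 15% of the empirical SD);
nested-F type-I error over 200 null replicates; and regression
recovery over 200 cohorts of 2000 respondents.  For the latter, the
estimand is the *induced* coefficient vector — thresholding the latent
scale attenuates the latent betas, so the truth is defined as the OLS
projection in a 100 000-respondent cohort, and each coefficient's 2-SE
interval must cover it in at least 93% of replicates.  End-to-end
recovery sets the person and day variances equal and requires the
pipeline's pooled net-affect ICC at n = 1000 to land within 0.07 of
the same statistic computed on a 100 000-respondent cohort, plus a
rank-monotonicity check that raising one activity's latent offset
raises its recovered rank.

## Known limitations

* The Delta coefficient is implemented for 2×2 tables only, with the
  uniform-guessing identification described above; K = 3 items are
  handled by weighted kappa, and other Delta variants are out of
  scope.
* The regression offers no survey weights, robust errors, or mixed
  effects; it mirrors the published OLS analysis.
* The ICC is the one-way single-measure form only; two-way mixed or
  consistency variants are deliberately not provided.
* Companion codes are carried by the data model but not analysed.
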