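---
title: "Decoding colour–emotion associations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding colour–emotion associations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gewmvpa)
```

This vignette documents the statistical machinery of `gewmvpa`: what is being
estimated, under which assumptions, which knobs matter, and where the design
was genuinely open.

## The decoding rationale

The data are Geneva Emotion Wheel (GEW) ratings: each participant rates the
association of 12 colour terms with 20 emotion terms on a 0–5 intensity scale
(0 = no association). Two decoding tasks turn "are associations systematic?"
into a measurable quantity:

* **Colour task.** One instance per (participant, colour): 20 features (the
  emotion ratings for that colour), label = the colour term. If emotion
  profiles are colour-specific *and consistent across participants*, a
  classifier can predict the colour of a held-out participant's rating
  vector above the 1/12 guessing rate. Accuracy is the measure of
  specificity/consistency; it is a lower bound, since classifier imperfection
  only lowers it.
* **Country task.** One instance per participant: all 240 ratings
  (colour-major order), label = country. Above-chance accuracy quantifies the
  country-specificity of the associations.

A third measure, the **in-group advantage**, asks how much better country
j's colour ratings are decoded by a classifier trained (with cross-validation)
on country j than by one trained on country i:
`D[i, j] = A[j, j] − A[i, j]`, summarised by its mean, sd (n−1), min and max
over the K(K−1) ordered pairs.

## The classifier and its evaluation

The decoder is an error-correcting output-code (ECOC) ensemble of binary
RBF-kernel support vector machines with **one-vs-one coding**: all 66 class
pairs for 12 classes. One-vs-one is the standard ECOC default at this class
count and sample size; each binary learner sees a balanced two-class
subproblem. Decoding is **loss-weighted**: for a row with binary decision
values `f_l`, class k's loss is the mean hinge loss `max(0, 1 − m_kl f_l)/2`
over the learners in which k participates, and the predicted class minimises
it. Per-class *scores* are the negated losses; they are used only through
their ranks (AUC), so any monotone transform is equivalent.

Binary learners come from `e1071::svm` (libsvm). libsvm's decision-value sign
depends on label order of appearance, so each learner's orientation is
calibrated once on its own training predictions and stored; this makes
prediction independent of row order.

**Uniform prior.** With unequal country sample sizes, each binary learner
weights its two classes inversely to their training frequencies
(`class.weights`), so the decision is not tilted towards the prevalent class.
AUC is additionally reported in both prevalence-weighted and macro (equal
class weight) form, because the published convention ("weighted average")
leaves the colour-task weighting ambiguous; with balanced classes — as in the
colour task, where every participant contributes one row per colour — the two
coincide.

**Participant-grouped cross-validation.** Folds partition *participants*
(sizes differ by at most one), never rows: a participant's 12 colour rows
share idiosyncrasies, and splitting them across folds would leak identity
into the test set and inflate accuracy. The engine asserts disjointness on
every fold of every run and refuses to proceed otherwise. Default k = 10.

**Hyperparameters.** Cost `C` and RBF width `gamma`
(`exp(-gamma * ||u − v||^2)`). The default grid is
C ∈ {0.1, 1, 10, 100} × gamma ∈ {0.001, 0.01, 0.1, 1}; ties break towards
smaller C, then smaller gamma (a mild preference for smoother models). It is
not stated in the source protocol whether tuning happened inside each fold or
once globally; the package defaults to **nested tuning** (an inner 5-fold
grouped CV inside each outer training set), which avoids optimistic bias, and
offers `tune = "global"` to mimic the cheaper protocol. A singleton grid
skips tuning; the package's own test suite mostly fixes `C = 10` with
`gamma ≈ 1/(2d)` (0.02 for 20 features, 0.002 for 240) — the standard
median-heuristic scale for features on a common 0–5 range — to keep runtimes
at desk scale. Features are *not* standardised by default: they already share
the 0–5 scale, and avoiding fold-dependent scaling state keeps runs exactly
reproducible.

**Permutation inference.** The null distribution of accuracy/AUC is obtained
by shuffling class labels and re-running the entire cross-validation
(default `n_perm = 10`). Labels are permuted at the row level for the colour
task and at the participant level for the country task, preserving the
grouping structure the CV respects. The p-value is the add-one estimator
`(1 + #{null ≥ observed}) / (1 + n_perm)`; with 10 permutations its floor is
1/11 ≈ 0.091, so a secondary z-statistic (observed AUC against the null mean
and sd, two-sided normal p) is reported alongside, clearly labelled as
secondary — it assumes an approximately normal null and should not replace
the exact estimator when `n_perm` is raised.

## Similarity from confusions

Colours with similar emotion profiles get confused. Luce's biased-choice
model writes the probability of responding j to stimulus i as proportional to
`b_j * eta_ij` with symmetric `eta`, `eta_ii = 1`. The moment estimator

```
eta_ij = sqrt( (p_ij * p_ji) / (p_ii * p_jj) )
```

on the row-normalised confusion proportions cancels the response biases and
row normalisers exactly, so on confusions sampled from the model it is
consistent (the test suite demonstrates RMSE < 0.02 at 10^5 choices per row).
A maximum-likelihood refinement exists but is not implemented; the moment
estimator is the classic closed form and the bias vector `b` (geometric mean
of `p_ij / eta_ij` per column, normalised) is reported for transparency.
Numerical choices: additive smoothing of 0.5 counts per cell by default
(sparse 12-class confusion matrices contain zeros and the estimator divides
by diagonals; the estimator is scale-invariant, so smoothing is the only
non-trivial choice), and estimates above 1 — possible under model misfit —
are clipped to 1 with a warning and recorded in the result.

## The synthetic-data generator

The generator emulates the structure of multi-country GEW data so the
pipeline is testable without the survey:

* a universal cell effect `U[k, e] ~ N(0, s²)` shared by all countries
  (`colour_specificity` s) — colour-specific emotion profiles;
* a country deviation `V[c, k, e] ~ N(0, δ²)` (`country_divergence` δ) —
  smaller, culture-specific departures;
* a participant propensity offset `a_p ~ N(0, ρ²)` (`heterogeneity` ρ);
* zero inflation: a cell is associated with probability
  `squash(logit(base) + U + V + a_p)` where `squash` is a logistic clipped to
  [0.02, 0.98] (the floor avoids degenerate all-0/all-5 cells; it can be
  disabled), `association_base = 0.3` by default so "no association" is the
  dominant response, as in real GEW margins;
* graded intensity among responders: `1 + Binomial(4, mu)` with
  `mu = 0.1 + 0.8 * plogis(conc · (U + V))`. The zero-inflated binomial was
  chosen because real GEW marginals show a dominant zero category with graded
  intensities among responders; any bounded ordinal family would do, and the
  binomial needs only the single `intensity_concentration` parameter `conc`,
  which scales how sharply intensity means vary across cells (default 1).

Defaults: 4 countries × 180 participants (≈ 720, the scale of a
multi-country online rating study), s = 1, δ = 0.5, ρ = 0.5. Seeding is
hierarchical: every participant draws from a substream derived from the
global seed, so the first m participants of a run are identical for any
n ≥ m, and subsets are reproducible independently.

What the generator does **not** emulate: real response styles (straight-
lining, scale anchoring), item non-response, translation effects across
languages, demographic structure (age/gender are uninformative placeholders),
or the particular published marginal distributions. Passing tests on
simulated data therefore demonstrate that the *machinery* is correct and
calibrated (chance-level behaviour under no signal, detection under strong
signal, advantage ≈ 0 under exchangeable countries); they do not certify
effect sizes on real survey data.

## Problem sizes and calibration checks

The test suite exercises the pipeline at sizes chosen to make the
statistical claims sharp while staying desk-scale: null calibration uses
200 participants (2400 colour-task rows; permuted labels must decode at
8.33% ± 3 points, AUC 0.5 ± 0.03), signal detection uses s = 2 (accuracy
must exceed 3× chance) and δ = 2 at 150 participants per country (country
accuracy must exceed 45%), and the δ = 0 transfer check uses 2 × 150
participants (|mean advantage| < 3 points). The advantage arithmetic is also
verified against a published four-country accuracy panel, whose 12
differences must reproduce to ±0.001 with mean 6.1% and sd 2.2%.

## Known limitations

* Only SVM-ECOC is provided; other learners may decode better, so accuracies
  are lower bounds on association consistency.
* No probability calibration: scores are rank-valid (for AUC) but not
  probabilities.
* The permutation floor of 1/11 at the default `n_perm = 10` makes "p < 0.05"
  unattainable without raising `n_perm`; the secondary z-statistic is a
  stop-gap, not a substitute.
* The biased-choice moment estimator assumes the confusion process follows
  the model; clipping events (`eta > 1`) flag misfit.
* With very small countries (fewer participants than folds) the transfer
  analysis refuses to run rather than silently degrading.
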