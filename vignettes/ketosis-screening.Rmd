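---
title: "Screening dairy cows for subclinical ketosis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening dairy cows for subclinical ketosis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketodetect)
```

## The screening problem

Subclinical ketosis (SCK) is defined biochemically: a blood
ß-hydroxybutyrate concentration strictly above 1.2 mmol/L in the first days
of lactation (`label_from_bhb()` applies this rule to day-3/5/8
measurements; exactly 1.2 counts as healthy). Blood testing every fresh cow
is expensive, so the package predicts the label from two data sources that
accrue automatically: five hourly accelerometer behaviour streams over the
week before or after calving, and up to 20 health/location/climate
features, many of them missing for a substantial share of animals. The
class structure is strongly imbalanced (the default cohort carries 15.80 %
sick animals), which shapes several choices below.

## The dissimilarity and its trained weights

Two equal-length series are compared by a double sum over *all* hour pairs,

$$D(a,b) = \Big(\sum_{i=1}^{n}\sum_{j=1}^{n} |a_i - b_j|^p\, g(i,j)\Big)^{1/p},$$

rather than hour-by-hour only. The off-diagonal terms let the measure
reward or penalise cross-hour relationships (say, night rest versus
afternoon activity) that a plain Minkowski distance never sees. The weights
are learned: with healthy and sick training mean series $\bar h,\bar s$,

$$G_{ij} = \mathrm{sign}\big(\min\{|\bar h_i-\bar s_j|,|\bar s_i-\bar h_j|\}
  - \max\{|\bar h_i-\bar h_j|,|\bar s_i-\bar s_j|\}\big),$$

so an entry is $+1$ exactly when the between-class contrast at hours
$(i,j)$ dominates the within-class one. $\mathrm{sign}(0)=0$ (standard
signum); this matters in the degenerate case of coinciding class means,
where $G$ is the zero matrix. $G$ is symmetric by construction and the
implementation verifies entries lie in $\{-1,0,1\}$.

Because a signed $G$ alone can behave erratically on noisy streams, it is
blended with the identity, $G(\lambda) = (1-\lambda)G + \lambda I$. The
convention is chosen so that $\lambda$ reads as "trust in the plain
Manhattan distance": $\lambda = 0$ uses the trained matrix unchanged and
$\lambda = 1$ recovers the Manhattan distance exactly (a tested property).
$\lambda$ is searched over the 31-value dyadic grid
$\{2^{-i}\}\cup\{1-2^{-i}\}$, $i = 0\ldots 15$ — dense near both endpoints,
where the behaviour changes fastest, and containing $0$, $0.5$ and $1$.

Metric behaviour is *not* claimed for general weights (signed sums can even
be negative; the nearest-centroid rule only compares them). For diagonal
weights with positive entries and $p \ge 1$ the function is a genuine
metric, and the test suite exercises all four axioms on $10^4$ random
triples. The pipeline fixes $p = 1$; general $p$ is kept in the library but
rejects negative weights, whose $p$-th roots would be undefined.

## The three-step classifier

**Step 1 — per-stream $\lambda$.** For each behaviour stream the
leave-one-out balanced error ($1 - (\mathrm{Sens}+\mathrm{Spec})/2$; the
balanced form is essential under 16 % prevalence) of a nearest-centroid
classifier is evaluated at every grid $\lambda$, and the minimiser is kept,
ties going to the *largest* $\lambda$ (closest to the well-understood
Manhattan regime). Two implementation notes, both covered by oracle tests:
the held-out animal's class centroid is removed by the exact mean downdate
$(n\bar x - x)/(n-1)$, equivalent to recomputation; and the sign matrix is
built once per training fold rather than inside every leave-one-out split —
it is a one-time construction from the training set, and per-split
rebuilding (available via `rebuild_sign = TRUE`) changes little but costs a
factor of 31. Because the blended distance is affine in $\lambda$, one pass
of sufficient statistics scores the whole grid; the naive re-evaluation is
kept in the tests as the oracle.

**Step 2 — ensemble vote.** The five stream classifiers vote; an animal is
labelled only on $\ge$ 4-of-5 agreement (`votes_required = 5` gives the
strict unanimous variant, which never decides more animals — a tested
monotonicity). Any missing stream makes the animal undecided rather than
voting on partial sensor data. Exact distance ties classify as sick: in a
screening context the cost of missing a ketotic cow exceeds that of one
unnecessary blood test. Both rules are configurable.

**Step 3 — feature route.** Undecided animals fall through to the feature
classifier: deterministic Relief (original two-class form, full pass over
all complete cases, min–max normalised, Manhattan neighbours) ranks the
features; an inner stratified 10-fold CV picks how many top features to
keep, maximising balanced accuracy with ties to the smallest count; and a
Gaussian naive Bayes produces the posterior. The sampled Relief variant was
rejected deliberately: with a few hundred training animals a full pass is
cheap and removes a source of run-to-run variation. The inner CV draws a
fresh stratification inside each outer fold (it does not try to reuse the
outer fold boundaries); when the complete-case subset of a class is smaller
than 10, the pipeline reduces the inner fold count to the smallest class
size.

The naive Bayes stage is the part built for missingness: moments are
learned per class and feature from whatever values are available (sample
variance, $n-1$), and at prediction time the likelihood terms of missing
features are omitted — masking a feature is *exactly* equivalent to a model
that never included it, an identity the tests assert to machine precision.
All features get Gaussian densities, including the $\pm 1$-coded parity:
one uniform treatment of the metricised features beats a special-cased
Bernoulli term for a single binary column. Class priors are empirical by
default (a `uniform` flag exists; the centroid stage is already
prevalence-invariant, so the prior mainly calibrates the posterior scale).
A variance floor of $10^{-9}$ times the largest per-class feature variance
guards constant features. The decision threshold on the sick posterior
defaults to 0.5 and can be retuned with `tune_threshold()` to guarantee a
target training sensitivity when the screen feeds a confirmatory test. An
animal with *all* selected features missing is undecidable; the pipeline
then applies the configured fallback label (default `healthy`, the majority
class) and reports the count.

## Evaluation

The outer loop is stratified 10-fold cross-validation; out-of-fold
predictions are pooled into a single confusion matrix (not per-fold
averaged — with ~10 sick animals per fold, per-fold measures are too
unstable to average meaningfully). The battery reports Acc, Sens, Spec,
balanced accuracy, Youden's $J$, Cohen's $\kappa$, F, precision, MCC, NPV
and Lift, with algebraic identities ($J = \mathrm{Sens}+\mathrm{Spec}-1$,
the F harmonic mean, $\mathrm{Lift} = \mathrm{Prec}/\mathrm{prevalence}$)
enforced by tests. One global seed fixes fold assignment and every sampled
quantity, so a report is a pure function of (data, config).

Feature screening uses the two-sided Mann–Whitney U test (exact for
tie-free groups of $\le 20$, normal approximation with tie correction
otherwise — behaviour-stream features are continuous, so the approximation
regime is the practical one) at the Bonferroni-corrected level
$\alpha/20 = 0.0025$. Sample SDs use the $n-1$ denominator.

## What the synthetic cohort does and does not emulate

No cow-level data are distributable, so the generator reproduces the
*statistical conditions* the method assumes, and the defaults are fixed at
the study's scale:

* **Labels**: Bernoulli at prevalence $106/671 = 15.80\,\%$ (or derived
  from simulated BHB curves via the 1.2 mmol/L rule when `emit_bhb = TRUE`,
  keeping the case definition exercised).
* **Features**: class-conditional Gaussians with the published per-class
  means and SDs for all 20 features, truncated to their natural ranges
  (BCS in $[1,5]$, ratios in $[0,1]$, non-negative times and
  concentrations) by redrawing tails; parity is a $\pm 1$ Bernoulli matched
  to the coded class means. Truncation biases the moments of strongly
  clipped features (heat-stress hours, mean 7 ± 12 truncated at 0, loses
  ~28 % of its mass; NEFA ~9 %), which is why the moment-recovery tests
  assert agreement only where the clipped mass is below 0.5 %.
* **Missingness**: MCAR at the published per-feature rates, with the
  recording structure made explicit — same-visit BCS/BFT pairs disappear
  together and the nine location features are masked as one block (a single
  data source), so the complete-case fraction (~44 %) that Relief sees is
  realistic.
* **Streams**: diurnal sinusoid + animal-level random intercept
  (SD 4 min/h) + hourly noise (SD 7 min/h) for lying and ruminating,
  clamped to $[0,60]$; the inactive/active/highly-active trio is drawn as a
  60-scaled three-part gamma composition around class-specific targets, so
  the 60-minute budget holds by construction rather than by clipping. No
  numeric class effects on behaviour are published, so the defaults are
  fixed once at values a herd-health practitioner would call plausible for
  SCK — sick offsets (min/h, post-partum week) lying $+2.5$, ruminating
  $-3.5$, inactive $+2.5$, active $-1.8$, highly active $-0.7$ (the trio
  offsets sum to zero to respect the budget), applied at 60 % strength in
  the pre-partum week to mirror the weaker pre-calving contrast. The
  animal-level intercepts matter: without them a weekly mean shift of a few
  min/h would be trivially separable over 168 hours.
* **Coupling**: streams and features are independent given the class by
  default; a single `severity_link` knob makes a per-animal severity
  multiplier shared between stream offsets and feature shifts, since the
  real within-animal correlation structure is unknown and should not be
  asserted.

What passing tests on these cohorts shows is that the pipeline recovers
class structure of the assumed form at the study's size, imbalance and
missingness — not that real accelerometer data satisfy those assumptions.
In particular the generator has no oestrus events, no management
disturbances, no day-to-day behavioural autocorrelation beyond the shared
sinusoid, and no informative missingness.

## Numerical and degenerate-input choices

* `sign(0) = 0`; coinciding class means give the zero matrix and the blend
  then degenerates gracefully toward pure Manhattan as $\lambda$ grows.
* Distance ties → sick; Relief weight ties → schema order;
  nearest-neighbour ties → lowest index; $\lambda$ ties → largest;
  feature-count ties → smallest; all deterministic.
* Leave-one-out needs two animals per class; Relief needs two *complete*
  animals per class; a selected feature must be observed twice per class —
  all enforced with informative errors.
* Series CSVs are validated on read: range $[0,60]$, activity budget within
  $10^{-6}$ of 60, duplicate (animal, hour) rejection, per-animal gap
  report. Hours are 0-based within each week; pre-partum hour 167 is the
  hour before calving, post-partum hour 0 the first after.
* Seeds: `generate_cohort`, `apply_missingness`, `stratified_kfold` and
  `run_experiment` take explicit integer seeds and restore the RNG state
  afterwards (`withr::with_seed`), so library calls never perturb a user's
  session RNG.

## Problem sizes in the test suite

The property suites run the full pipeline on cohorts of 600–671 animals
with 10 outer folds — the study's scale — for the permutation-null and
signal-recovery checks (20 replicates each), and use reduced cohorts
(80–120 animals, 24–48-hour weeks, 3–5 folds) for structural tests where
statistical power is not the point. Oracle comparisons (naive double-loop
distance, exhaustive $\lambda$ search, per-count naive Bayes refits) run on
toy sets of 6–60 examples where brute force is exact and fast.

## Known limitations

* The dissimilarity is $O(n^2)$ per pair (168² terms for weekly streams);
  the inner loop is in C++ and the $\lambda$ search reuses sufficient
  statistics, but very long series would need thinning.
* Lift is reported for completeness but is redundant given precision and
  prevalence; under heavy imbalance NPV is optimistic and should be read
  with care.
* The ensemble requires all five streams; animals with partial sensor
  weeks go straight to the feature route rather than voting on a subset.
* MCAR is an assumption of the generator, not a finding; if missingness on
  a real farm is informative (sicker cows measured more often), the
  complete-case Relief ranking can be biased in ways these tests will not
  reveal.
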