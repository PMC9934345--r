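---
title: "Forecasting adult height from growth curves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting adult height from growth curves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthcast)
```

## The problem

Predicting a child's adult stature from nothing but a series of annual height
measurements is a classic problem in auxology, paediatric endocrinology and
youth sport.  Radiological bone-age methods are accurate but invasive and
costly; anthropometric formulas need parental height or sitting height, which
are rarely available.  Height-only prediction has traditionally meant growth
charts: assume the child keeps its height-for-age percentile and read off the
adult height of that percentile.  That assumption fails exactly where
prediction matters most — during the adolescent growth spurt, whose timing
varies by several years between children.  A child measured mid-spurt sits at
a temporarily inflated percentile; a late developer sits at a deflated one.

`growthcast` implements a nearest-neighbour alternative, **Growth Curve
Comparison (GCC)**, together with the standard baselines it is compared
against, a discrete peak-height-velocity (PHV) detector, an evaluation
harness, and a parametric cohort simulator that provides ground truth.

## Data model and birthday alignment

Raw records are dated measurements (school programmes typically measure every
April, not on birthdays).  Because methods compare children *at the same
age*, each child's record is first linearly interpolated in time to the
heights at its integer-age birthdays (ages 8–18).  A birthday that falls
exactly on a measurement date takes the measured height; birthdays outside
the measured range are left missing — we never extrapolate.  At least two
measurements are therefore required before anything can be predicted.

Reference libraries (`reference_cohort`) keep only children with all eleven
ages 8–18 observed, separately for boys and girls; every model in the package
is fitted and queried within one sex stratum.

Small height *decreases* between consecutive ages (≤ 1 cm) are treated as
measurement noise; larger decreases flag the series with a warning but never
exclude it, since real stadiometer data contains occasional gross errors that
the analyst should see rather than silently lose.

## The GCC forecaster

Given a query child observed up to age $B$, GCC

1. computes the cosine similarity
   $k(x, y) = \dfrac{\langle x, y\rangle}{\lVert x\rVert\,\lVert y\rVert}$
   between the query's observed growth-curve vector and every same-sex
   reference child, restricted to the ages the query has observed (the
   method tolerates interior gaps for this reason);
2. keeps the $k$ most similar children (default $k = 100$; accuracy is flat
   over roughly 75–150, and larger $k$ only costs time);
3. for each future age $a \in (B, 18]$ takes the neighbours' mean annual
   increment $\overline{\Delta}_a = \operatorname{mean}_j\,
   \{h_j(a) - h_j(a-1)\}$ and predicts
   $\hat h(a) = h(B) + \sum_{u=B+1}^{a} \overline{\Delta}_u.$

Anchoring the sum on the query's *own* last height, rather than averaging
the neighbours' heights, is essential: for very tall or very short children
even the closest neighbours are systematically less extreme, so a
median-of-neighbours forecast would be biased toward the centre of the
distribution.  Summing increments transfers only the neighbours' *growth
pattern*, not their level.

### Numerical choices

* **Similarity basis.** The growth curve is, read literally, the vector of
  birthday heights, and that is the default (`similarity_basis =
  "heights"`).  Raw-height cosine similarity is weakly discriminative — all
  human growth curves point nearly in the same direction, so similarities
  crowd toward 1 — which is why the configuration also offers
  `"increments"`, the year-on-year growth vector, a sharper shape signature.
  Both produce valid retrievals; the default favours fidelity to the
  method's plain description, and all evaluation code works with either.
* **Tie rule.** Ranks are ordered by similarity, then by smaller absolute
  height difference at the anchor age, then by child id.  This makes
  retrieval fully deterministic and makes the degenerate single-age window
  well defined: with one observed height every similarity is exactly 1 and
  the rule reduces to "the $k$ nearest heights at that age", the natural
  single-value limit of the method (the evaluation grid includes such
  windows because forecasts from a single age-8 value are part of the
  protocol).
* **Self-exclusion.** A query whose id exists in the reference cohort never
  retrieves itself — required for honest leave-one-out evaluation, harmless
  in production.
* **Zero-norm vectors** (possible only under the increments basis for a
  perfectly flat curve) raise an explicit error rather than returning NaN.

### Confidence intervals

For every (last observed age $B$, target age $C$) pair the package forecasts
each cohort member from ages $8..B$ with that member excluded from the
neighbour pool, collects the residuals at $C$, and reports twice their sample
standard deviation (denominator $n-1$; the unbiased choice) as the 95%
half-width.  Residual distributions here are close to Gaussian, for which
$\pm 2\,\mathrm{SD}$ covers 95.4%; the acceptance suite verifies ~95%
empirical coverage on a freshly simulated cohort.  Whether such bands should
be calibrated in-sample or leave-one-out is a genuinely open choice; we use
leave-one-out everywhere so that the bands describe forecasts for unseen
children.

## Baselines

* **Percentile (rank preservation).**  One hundred integer percentile bins
  per age from the empirical stratum distribution; ties at bin edges fall to
  the lower bin; a queried height outside the observed range clamps to the
  extreme bin with a warning; empty bins borrow the nearest non-empty bin's
  mean.  The prediction is the mean age-18 height of the child's current
  bin.  During evaluation the query's own adult height is removed from its
  bin mean and its rank is taken among the other $n-1$ children (bin
  memberships of the others are kept from the full sample — recomputing all
  ranks per query changes third decimals at cohort sizes of interest and
  costs a factor of $n$).
* **Regression baselines** (`linear`, `tree`, `xgb`, `xgb_phv`) consume an
  engineered feature row computed strictly from the ages 8..$B$ prefix:
  current and previous height; growth in the last and second-to-last year
  (first derivative); mean, maximum and variance of annual growth;
  current percentile; growth minus the same-sex, same-interval population
  mean; the difference between the last two growths and the growth trend
  (second derivative — two encodings of the same quantity, kept for
  completeness; least squares handles the collinearity by pivoting); and
  the distance from age 18.  One model is fitted per (sex, $B$) cell,
  predicting height at 18 directly (predicting *remaining* growth is an
  equivalent reparameterisation we did not pursue).  A single-age prefix
  zero-fills the growth features and sets a flag; two ages zero-fill only
  the second-derivative features.
* **Hyperparameters.**  CART is depth-limited (`maxdepth = 6`,
  `cp = 0.001`) to temper the overfitting that unconstrained trees show on
  this problem; boosting uses 150 rounds, depth 4, learning rate 0.1,
  single-threaded so results are bit-reproducible under a seed.  No
  hyperparameter search is performed anywhere.

## PHV detection

PHV age is operationalised discretely: the starting age of the annual
interval with the largest height increment (ties resolved to the earliest
interval; the convention matches "the age at which PHV begins").  The
occurrence classifier sees one row per (child, interval) — ten rows per
complete curve, exactly one positive — with features describing local growth
change: the increment, the previous increment, their difference, and the
increment relative to the same-sex same-age population mean, plus an
indicator for "no previous interval".  Features use only heights up to the
interval's right endpoint, so a prefix ending at $B$ can score intervals
starting up to $B-1$ with no lookahead, which is what makes the estimate
usable as a forecasting feature.  The estimated PHV age of a prefix is the
earliest interval whose predicted probability crosses 0.5, or "not yet"
(encoded for the boosted regressor as sentinel 0 plus a `has_phv`
indicator, so both "PHV at 12" and "PHV still ahead" are representable).
The classifier is trained on simulator-labelled curves; a hand-labelling
step is unnecessary because the simulator provides exact ground truth.

## Evaluation protocol

For each window $A..B$ ($8 \le A \le B \le 17$) the harness predicts height
at 18 and reports the mean absolute error in millimetres.  GCC and the
percentile method are evaluated leave-the-query-out over all individuals;
the regression baselines use 5-fold cross-validation with folds assigned by
child (never by row) and with population statistics (percentile grids, mean
growth, PHV classifier) recomputed from each training fold.  Age-18 height
is treated as adult height — an acknowledged limitation inherited from the
data design, since many boys grow measurably after 18.

## The simulator

No suitable public longitudinal cohort exists, so the package ships a
generative stand-in with analytic ground truth.  Each child's noise-free
height is

$$h(t) = h_8 + c\,(t - 8) + A\,[s(t) - s(8)], \qquad
  s(t) = \frac{1}{1 + e^{-b (t - t_p)}}$$

a linear childhood trend plus a logistic pubertal spurt.  The velocity
$h'(t) = c + A b\, s(t)(1 - s(t))$ is strictly positive and maximal exactly
at $t = t_p$, so the true PHV age is a model parameter, not an estimate.
This form was chosen over Preece–Baines for the closed-form velocity peak.

Defaults (changeable through `sim_params()`):

| parameter | boys | girls | unit | rationale |
|---|---|---|---|---|
| adult height | N(180, 6.8) | N(167, 6.2) | cm | European school-cohort magnitudes |
| PHV age $t_p$ | trunc-N(12.5, 1.0) on [9.5, 16] | trunc-N(11, 1.0) on [8.5, 14.5] | yr | girls' spurts cluster at 10–12, boys' at 11–14 |
| baseline velocity $c$ | U(3.4, 4.4) | U(2.3, 3.3) | cm/yr | see below |
| spurt amplitude $A$ | U(10, 16) | U(8, 14) | cm | peak velocities ≈ 8–10 cm/yr |
| tempo $b$ | U(1.2, 1.8) | U(1.2, 1.8) | 1/yr | spurts last ≈ 2–4 yr |
| measurement noise | 0.5 | 0.5 | cm | stadiometer + posture error |

The curve is anchored at the *drawn adult height*: $h_8$ is back-solved so
that $h(18)$ equals the target, and implausible draws ($h_8$ outside
100–150 cm) are rejected and redrawn.  Two aspects of $c$ deserve note.
First, $c$ is the *average non-spurt* velocity over the whole 8–18 span, not
the instantaneous pre-pubertal velocity (real velocity declines through
childhood and stops after the spurt; a constant-plus-logistic model cannot
match both, and matching the total 8-to-18 gain — ≈ 52 cm for boys, ≈ 39 cm
for girls — is what keeps age-8 heights and adult heights jointly
realistic).  Second, its between-child spread (sd ≈ 0.29 cm/yr) sets the
childhood height-tracking correlation; the defaults yield age-8-to-18
correlations of about 0.83–0.89, in line with longitudinal growth studies.
With these two choices the simulator reproduces the qualitative structure
the methods are designed around: stable childhood percentiles, a
percentile-method error bump centred on the median PHV age that disappears
when PHV heterogeneity is switched off (`phv_age_sd = 0`), and GCC's
advantage concentrated in the pubertal years.

Measurements are dated April 15 ± 10 days in each calendar year in which the
child is between 7 and 19, with birthdays uniform over the year — so the
birthday-interpolation path is exercised realistically, and a small fraction
of children (≈ 1%) lack a bracketed age-8 or age-18 birthday and drop out of
the complete-curve subset, as in real cohorts.

**What the simulator does not model** — and therefore what passing tests do
*not* demonstrate about real data: secular height trends, family/twin
correlation, skewed or age-dependent measurement error, seasonal growth
variation, dropout correlated with height, late (post-18) growth, and any
non-logistic spurt shape (e.g. double spurts).  Conclusions supported by the
test suite are about the *correctness and internal behaviour* of the
methods, not about their accuracy on any particular human population.

## Problem sizes used by the test suite

The acceptance properties run on a simulated study cohort of 2,000 children
per sex (the size at which fold-to-fold and seed-to-seed variability of the
MAE curves is well below the effects being asserted), an 800-per-sex fresh
cohort for interval coverage, and a 200-per-sex cohort for the byte-level
reproducibility check of the full pipeline; retrieval and labelling oracle
checks use 200 random strata of up to 500 members and 10,000 random series
respectively.  The acceptance script uses 1,000 children per sex.

## Known limitations

* Adult height is height at 18 by definition of the data model.
* The regression baselines require gap-free prefixes starting at age 8;
  only GCC handles interior missing ages.
* The percentile leave-one-out evaluation keeps full-sample bin memberships
  for the non-query children (exact recomputation per query is an $O(n)$
  factor slower and numerically indistinguishable here).
* CI tables assume the residual spread of the reference cohort transfers to
  the query population; a query child from a different population voids the
  bands.
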