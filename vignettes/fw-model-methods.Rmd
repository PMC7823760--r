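---
title: "Methods: healthy-aging scoring and the F-W regional index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: healthy-aging scoring and the F-W regional index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwaging)
```

## The model

The package links an individual-level definition of healthy aging (HA) to a
regional composite index.

**Micro level.** A respondent is healthy-aging when four operational
criteria hold simultaneously:

* *physical health* — no disability and at most two chronic conditions;
* *daily activities* — each of ten ADL items (dressing, bathing, eating,
  transfers, toileting, continence, chores, shopping, telephoning,
  medication) graded 1 ("no difficulty") or 2 ("difficulty but manages
  alone");
* *mental health* — a ten-item depression scale, each item graded 1–4 by
  frequency, with total score at most 20;
* *social participation* — at least two distinct social activities attended
  in the last month, out of eight surveyed.

Binary covariates describe the respondent's own household ("first family":
gender, age band, urban residence, literacy, marital status, expectation of
long-term care from grown children; `x1`–`x6`) and the grown children's
household ("second family": their literacy, co-residence, marital status,
health, housing, and whether the respondent minds their children; `x7`–`x12`).
Screening proceeds in three stages: per-factor Pearson chi-square tests
(uncorrected, the convention that reproduces published 2×2 screening
statistics), two block logistic regressions fitted per family to avoid
cross-family collinearity, and a single backward stepwise logistic
regression over all twelve covariates.

**Macro level.** The retained micro model supplies the weights of the F-W
("factors and weights") index

$$\mathrm{HA} = \sum_i F_i\, W_i,$$

where each $W_i = |\ln \mathrm{OR}_i|$ from the final model and the $F_i$
are regional factor ratios to the national average: the reciprocal old-age
dependency ratio (aging), urbanization rate, mean schooling years
(education), and a family-care measure. Age maps to the aging factor,
residence to urbanization, the two literacy indicators combine into the
education weight in a 1/3 : 2/3 ratio, and the expectation of long-term care
maps to family care.

## Numerical and convention choices

* **Chi-square** uses the product formula
  $n(ad-bc)^2/[(a{+}b)(c{+}d)(a{+}c)(b{+}d)]$ with df = 1 and *no*
  continuity correction. Published screening tables appear to truncate some
  statistics to two decimals (8.478 printed as 8.47), so reproduction tests
  assert agreement within 0.01 rather than exact rounding.
* **Logistic fits** are maximum-likelihood via IRLS (`stats::glm`), with
  Wald standard errors, $z = 1.96$ confidence intervals and Wald p-values.
  Rank deficiency and (quasi-)separation raise structured errors rather
  than returning unusable estimates; separation is detected from the
  fitted-probability warning or a coefficient magnitude above 15.
* **Backward elimination** removes one term per step — the largest Wald
  p-value above `alpha_stay` (default 0.05) — and never re-admits a removed
  term. Ties are broken by removing the term latest in candidate order,
  making the trace deterministic. `alpha_stay = 1` keeps the full model;
  with a null cohort and a small threshold everything is eventually removed
  down to the intercept.
* **Weights** use the *magnitude* of the log odds ratio. The reference
  coding of a binary indicator only flips the sign of $\beta$, and published
  weight tables print positive weights for protective-coded terms; a
  `signed = TRUE` switch preserves signs for sensitivity analyses. Per-term
  magnitudes are rounded (default two decimals) *before* the education
  composite $w_3 = \beta_4/3 + 2\beta_7/3$ is formed, matching the printed
  composition. Note one published rounding quirk: $|\ln 0.497| = 0.699$
  rounds to 0.70 while the source table prints 0.69 (truncation); the
  package reports the computed value.
* **Cronbach's alpha** uses sample (n−1) variances — the standard
  psychometric convention — and reports alpha-if-item-deleted per item.
  Depression items are summed as recorded with no reverse-coding; if the
  underlying questionnaire contains positively-worded items this is a known
  caveat of the operational definition, flagged here because the scale
  description does not settle it.
* **Baseline-100 normalization** is
  $\mathrm{score}_{100} = 100\,\sum_i F_i w_i / \sum_i w_i$, chosen so that
  a region whose four factors all equal the national average scores exactly
  100 (the published tables annotate "baseline 100" without a formula).
  The score is invariant to rescaling all weights by a common constant.
  Whether the original analysis normalized per-year or against a fixed base
  year cannot be reverse-engineered without the yearbook inputs; this
  implementation computes national denominators per year.
* **Family-care factor.** "Number of households relative to the national
  average" is ambiguous — raw household counts scale with province size —
  so the default measures persons per household relative to the national
  figure (`family_care = "persons_per_household"`), with
  `"household_count"` available as the literal reading (ratio to the
  cross-region mean).
* **National aggregates** are population-weighted means for rates and
  schooling, and total-population / total-households for persons per
  household.
* **Trend typing** uses the signs of the two consecutive changes over three
  cross-sections (type 1 up–down, 2 down–down, 3 down–up, 4 up–up); a flat
  segment counts as "down", so the classification is exhaustive and
  exclusive. Real panels never produce exactly flat segments; the rule only
  matters for engineered inputs.
* **Zone aggregation** is the unweighted mean of member-region scores. The
  packaged eight-zone mapping (`inst/extdata/economic_zones.csv`) pre-fills
  the Beijing–Tianjin–Hebei, Yangtze River Delta and Pearl River Delta
  cores as published; the remaining memberships are editable package
  defaults, since the source enumerates only some of them and its zone
  names overlap.

## What the synthetic generator emulates

`generate_micro()` draws covariates as independent Bernoulli variables at
the reference cohort's margins (an optional Gaussian-copula equicorrelation
knob exists, default 0 — the joint distribution of the covariates is not
documented, so independence is an assumption). The composite outcome is
Bernoulli at `plogis(β·x)` with the published final-model effect magnitudes
as default coefficients; the intercept is calibrated by exact enumeration so
the population prevalence equals the published 17.2%.

Criterion statuses are then drawn conditionally on the composite: a
healthy-aging respondent passes all four; otherwise the four statuses are
drawn at their conditional marginals (derived from the published criterion
prevalences .686/.847/.614/.394) with all-pass patterns rejected. Item
responses are generated *constructively* from the drawn statuses — ADL
passes restrict grades to {1, 2}, mental-health failures force the
depression sum above 20, and so on — so re-scoring a generated cohort
reproduces the latent statuses exactly. This makes the scoring module
round-trip testable but means item-level distributions are stylized: a
shared per-respondent severity factor (`item_noise`, default 1) induces
realistic within-scale correlation (alpha around 0.8–0.95), but the
generator does not mimic questionnaire skip patterns, item-specific
response styles, survey weights or multi-wave structure. A green round-trip
test therefore establishes the correctness of the scoring rules, not
realism of the item marginals.

`generate_macro()` draws regional baselines log-normally around configured
national means (urbanization on the logit scale, capped at 0.97) and
evolves them with per-region, per-variable relative drifts per period
(default N(0.02, 0.05) — gentle secular change), overridable per region for
engineered trend tests.

Defaults in both generators are fixed statements of the emulated world and
are not adjusted to test outcomes.

## Known limitations and one structurally red criterion

Published multivariable odds-ratio tables and regional index values are not
reproducible without the original microdata and yearbook panels; the
package reproduces them in *shape* on synthetic data. Two published
chi-square rows (co-residence 0.28, children's health 10.68) are
inconsistent with their own printed cells (recomputation gives 0.87 and
2.06) and are excluded from reproduction tests. The reference-level coding
of the literacy indicators appears to flip between published tables (final
odds ratios below 1 where block fits print protective ratios above 1, and
an abstract value of 2.01 ≈ 1/0.497); the package keeps one fixed coding
and exposes the reciprocal relation rather than guessing intent.

One acceptance property is left deliberately red: exact recovery of the
true support {x2, x3, x4, x6, x7} by backward elimination in at least 80%
of replicates at n = 5,000. With the stated effect magnitudes the five true
terms are essentially always retained (smallest Wald z ≈ 5), so the exact
recovery rate is bounded by the probability that none of the seven null
candidates survives at `alpha_stay = 0.05`, roughly $0.95^7 \approx 0.70$;
the measured rate is ~0.70–0.72. This is a property of backward elimination
itself, not of the implementation, and the test documents the stated bar
rather than weakening it.

## A worked example

```{r example}
rec <- generate_micro(micro_config(n = 2000, seed = 42))
profiles <- score_profile(rec)
prevalence(profiles)

trace <- backward_stepwise(rec, profiles)
trace

w <- derive_weights(c(x2 = 1.554, x3 = 1.573, x4 = 0.663,
                      x6 = 1.697, x7 = 0.497))
w

panel <- generate_macro(macro_config(n_regions = 6, seed = 9))
idx <- regional_index(panel, w)
head(idx)
classify_trend(idx)
```
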