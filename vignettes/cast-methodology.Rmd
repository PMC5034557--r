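---
title: "Assessing community capacity for substance-abuse care with castr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing community capacity for substance-abuse care with castr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castr)
```

## The problem and the model

Community needs assessments describe local behavioral-health burden but
rarely say *how many* programs, providers, or beds a community should have.
CAST (calculating for an adequate system tool) answers that question for a
substance-abuse care system organised along a five-category continuum of
care — promotion, prevention, referral, treatment, recovery — comprising 32
concrete components (drug courts, 12-step meetings, inpatient
detoxification, ...). For each component the recommended number of units is

$$\textrm{Community Need} \;=\; \frac{X_1 \times Y_1}{Z_1} \times (1 + R)
\times U$$

* $X_1$ — the component's target population, resolved from the community
  profile by a selector (total population, an age band, or the expected
  substance-using population: persons aged 12–65 times the expected
  substance-use prevalence, a user-supplied scalar standing in for a
  subregional survey estimate).
* $Y_1$ — individual dosage frequency per year; $Z_1$ — participants served
  per unit. $(X_1 Y_1)/Z_1$ is the *maximum* need: full coverage of
  everyone who might interact with the component.
* $R$ — the social/community risk term, the sum of the two groups'
  *prevalence ratios*: the fraction of the 11 social and of the 7 community
  county-level indicators whose measured values cross their published
  thresholds.
* $U$ — the usage rate, the fraction of the eligible population expected to
  actually use the component. An adequate system serves the accessing
  population, not the entire at-risk population.

All three multiplicative factors commute, so the engine forms a single
product and rounds once, at the end (`half_up` by default; `ceiling` is
available for conservative capacity planning). Gaps are recommended minus
observed units, kept signed: positive is a shortfall, negative a
redundancy.

## The risk multiplier: two readings, one default

The source method prints the risk adjustment as $(1 + R)$, yet its own
two-community worked example displays risk scores of 0.78 and 1.06 — values
below 1, whose *ratio* (1.06/0.78), not the ratio of $1+R$ values, scales
every printed pair of unit counts. The package therefore implements both
readings and defaults to the one that reproduces the worked example:

* `mode = "score"` (default): multiplier $= R \in [0, 2]$;
* `mode = "equation"`: multiplier $= 1 + R \in [1, 3]$, the literal
  equation.

Brute-force enumeration over all flag counts $k_s \in 0..11$,
$k_c \in 0..7$ shows that $7/11 + 1/7 = 0.7792$ and $7/11 + 3/7 = 1.0649$
are the *unique* decompositions displaying 0.78 and 1.06 at two decimals —
this fixes the synthetic worked-example profiles at exactly those flag
counts.

Indicator flags use strict inequalities, exactly as the thresholds are
published ("voter turnout <35%", "violent crime rate >300 per 100,000"); a
value at the threshold never flags. Three indicators (median income
> $53,000, college-degree share >30%, exercise access >50%) look
protective but are implemented as published: exceedance flags. Unmeasured
indicators are excluded from numerator and denominator with a warning
(`missing_policy = "exclude"`); strict runs can demand completeness with
`"error"`. Demographics are profile fields, never risk flags.

## Full-precision vs displayed multipliers

By default the full-precision multiplier (e.g. $60/77 = 0.779221$) flows
through the computation and the two-decimal score is display only. The
worked example, however, is *only* reproducible with the displayed scores:
inverting the final rounding shows that the printed pair (64, 86) for peer
support groups admits **no** common base need under the full-precision
multipliers, while all 32 pairs do under 0.78/1.06. The original
calculations evidently applied the rounded score. `assess_community()`
exposes `multiplier_digits` for this; the shipped worked-example fixture
runs with `multiplier_digits = 2`, and everything else defaults to full
precision.

## Reconstructing the worked example

The per-component parameter values behind the published example were never
printed. `worked_example()` instead inverts the arithmetic: for each
printed pair $(a, b)$, the set of base needs $B$ with
$\mathrm{round}(0.78B) = a$ and $\mathrm{round}(1.06B) = b$ is the
intersection of two half-open rounding preimages
$[(v-\tfrac12)/m, (v+\tfrac12)/m)$. Every one of the 32 intersections is
non-empty (an empty one would abort, so the constructor doubles as a
validation), the midpoint is taken as the base need, and the fixture's
parameter table back-solves it into a dosage frequency with unit group
size and usage rate over the shared population of 50,000. Running the full
pipeline on the fixture reproduces all 64 printed unit counts exactly —
the package's headline test.

```{r}
wx <- worked_example()
rep_b <- assess_community(wx$profile_b, component_registry = wx$components,
                          multiplier_digits = 2)
all(rep_b$recommended_units == wx$pairs$value_b)
rep_b[rep_b$component_id == "twelve_step",
      c("name", "recommended_units", "unit_label")]
```

## What the synthetic generator does and does not emulate

`generate_profile(seed, k_social, k_community)` draws each indicator value
uniformly from a band strictly on the requested side of its threshold
(5%–50% away), so the requested flag counts are achieved by construction,
under a fixed, caller-preserving seed. Shared demographics are a
plausible stated world: 70% aged 12–65, 13% aged 10–19, 60% aged 20–65,
49% male, 10% substance-use prevalence. The generator does **not** emulate
inter-indicator correlation (income vs insurance coverage), spatial
structure, or measurement error, so a green test establishes the
arithmetic of scoring and need calculation — not that any real county's
data would flag this way.

## Default component parameters are placeholders

The published calculator's per-component $Y_1$, $Z_1$, $U$ and selectors
live in an unavailable spreadsheet appendix. The shipped table
(`inst/extdata/components_synthetic_defaults.csv`, deliberately labelled
synthetic) preserves the published component list, categories, and unit
labels but carries documented placeholder parameters chosen to be
order-of-magnitude sensible (e.g. one campaign per 25,000 residents;
detoxification admissions at $Z_1 = 1$ person per admission). Every
computation reads parameters from the file; users doing real planning
should override them with locally sourced values via
`default_components(overrides = ...)` or their own CSV.

## Monte Carlo sensitivity

The stability analysis sketched alongside the method is implemented as:
each replication multiplies every component's $Y_1$, $Z_1$, $U$ by
independent lognormal noise ($\mathrm{meanlog} = 0$, relative scale
`perturbation_scale`, default 0.1), clamps back to valid ranges
($Z_1 \ge 1$, $U \le 1$), recomputes all 32 recommendations, and reports
empirical percentile intervals (95% by default, configurable). Which
quantities to vary was left open in the source; this implementation
perturbs the component parameters and offers `perturb_thresholds = TRUE`
to also jitter indicator thresholds and re-derive the risk score per
replication. Zero scale collapses the intervals to the point estimates,
and a fixed seed is bitwise reproducible.

## Numerical choices and edge cases

* Rounding is half-up (0.5 rounds away from zero), applied exactly once;
  the printed pairs are inconsistent with any single rule applied to
  $a/0.78$, implying independent rounding of an unprinted base need under
  each multiplier — which is what the reconstruction assumes.
* An indicator group with no evaluable members yields a prevalence ratio
  of 0 with a warning rather than NaN.
* A zero-population community yields zero recommended units everywhere.
* $X_1$ stays real-valued; only final recommendations are integers.
* Registry files are CSV (a YAML reader is not among the package's
  dependencies); reports write as CSV, JSON (round-trippable, with
  provenance: mode, rounding, multiplier, registry checksums, optional
  timestamp disabled by default so identical runs are byte-identical), or
  markdown.

## Known limitations

Recommendations inherit the quality of the placeholder parameters and of
the user-supplied prevalence scalar; thresholds are single published
cutoffs, not ranges; all indicators within a group weigh equally; and the
tool stops at unit recommendations — no costing, prioritisation, or claims
about resulting changes in substance-abuse rates.
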