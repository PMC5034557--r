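# castr

Community capacity assessment for substance-abuse care.

Community needs assessments and health rankings describe local
behavioral-health burden, but they do not tell a health department *how
many* drug courts, 12-step meetings, detoxification beds, or prevention
programs its community should have. `castr` implements CAST (calculating
for an adequate system tool), a needs calculator that turns a community's
demographic, social, and community risk profile into recommended unit
counts for 32 care-system components across the five continuum-of-care
categories (promotion, prevention, referral, treatment, recovery), and
compares them with observed inventory to expose shortfalls and
redundancies. It is written for public-health practitioners and analysts
doing community-level capacity planning.

## The model

For each component, the recommended number of units is

```
Community Need = [(X1 x Y1) / Z1] x (1 + R) x U
```

* `X1` — target population (a selector over the profile: total population,
  an age band, or expected substance users = population aged 12–65 x
  substance-use prevalence);
* `Y1` — individual dosage frequency per year; `Z1` — participants served
  per unit, so `(X1 x Y1)/Z1` is the maximum need at 100% coverage;
* `R` — social/community risk: the fraction of 11 social indicators plus
  the fraction of 7 community indicators whose county-level values cross
  their published thresholds (strict inequalities);
* `U` — usage rate, the fraction of the eligible population expected to
  actually use the component.

Two multiplier readings are implemented: `mode = "score"` (default,
multiplier `= R`, which reproduces the published worked example's risk
scores 0.78 and 1.06) and `mode = "equation"` (multiplier `= 1 + R`, the
literal equation). See the methods vignette
(`vignettes/cast-methodology.Rmd`) for why both exist.

## Worked example

```r
library(castr)

# synthetic community of 50,000 flagging 7/11 social + 1/7 community indicators
profile <- generate_profile(seed = 1, k_social = 7, k_community = 1)
assess_risk(profile)
#> <cast_risk> mode = score
#>   social:    7/11 flagged (ratio 0.6364)
#>   community: 1/7 flagged (ratio 0.1429)
#>   multiplier 0.779221 (displayed risk score 0.78)

report <- assess_community(profile)
category_summary(report)
#> # A tibble: 6 x 3
#>   category   n_components recommended_units
#>   <chr>             <int>             <int>
#> 1 promotion             3                19
#> 2 prevention            7               130
#> 3 referral              6                18
#> 4 treatment             7               270
#> 5 recovery              9               268
#> 6 total                32               705
```

The risk score 0.78 is the sum of the flagged fractions (7/11 + 1/7 =
0.7792, displayed to two decimals); each category row sums the
recommended integer unit counts of its components under the shipped
(placeholder) parameter table — 705 units in total for this community.
Replace the placeholders with locally sourced parameters via
`default_components(overrides = ...)` before drawing real conclusions.
Add observed inventory with `gap_analysis()`, and quantify parameter
uncertainty with `sensitivity_mc()` (seeded lognormal perturbation of
Y1/Z1/U, percentile intervals).

The published two-community worked example is reconstructed by
`worked_example()`; assessing its profiles with `multiplier_digits = 2`
reproduces all 64 printed unit counts exactly (see
`tests/testthat/test-acceptance.R`).

## Command line

```sh
Rscript inst/cli/cast.R fixtures --out-dir fixtures/
Rscript inst/cli/cast.R assess --profile fixtures/community_a.json \
  --components fixtures/components_worked_example.csv \
  --multiplier-digits 2 --out report.json
Rscript inst/cli/cast.R validate --profile fixtures/community_a.json
```

Subcommand `assess` writes CSV/JSON/markdown reports (format guessed from
the extension); `validate` checks input files without writing; `fixtures`
emits the worked-example profiles, parameter table, and expected units.

## Acceptance script

`scripts/acceptance.R` recomputes the two anchor quantities from scratch —
the displayed risk scores of synthetic profiles flagging exactly 7/11
social + 1/7 community and 7/11 + 3/7 indicators — by generating the
profiles, scoring them against the shipped registry, and running the full
need pipeline:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
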