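Package: castr
Title: Community Capacity Assessment for Substance Abuse Care (CAST)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements CAST (calculating for an adequate system tool), a
    needs calculator for community substance-abuse care systems. Given a
    community profile (population, age structure, substance-use prevalence,
    and measurements of 18 county-level social and community indicators),
    the package computes a social/community risk multiplier, applies the
    need equation Community Need = [(X1 x Y1)/Z1] x [1 + R] x U to each of
    32 care-system components across the five continuum-of-care categories
    (promotion, prevention, referral, treatment, recovery), and reports
    recommended unit counts, gaps against observed inventory, and Monte
    Carlo sensitivity intervals. Includes a seeded synthetic-profile
    generator and a reconstruction of the published two-community worked
    example for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
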