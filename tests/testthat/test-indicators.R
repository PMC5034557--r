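test_that("shipped indicator registry has 11 social and 7 community definitions", {
  reg <- default_indicators()
  expect_equal(sum(reg$group == "social"), 11)
  expect_equal(sum(reg$group == "community"), 7)
  expect_equal(anyDuplicated(reg$id), 0L)
  bool <- reg$kind == "boolean"
  expect_true(all(is.na(reg$threshold[bool])))
  expect_true(all(!is.na(reg$threshold[!bool])))
})

test_that("indicators flag on strict threshold comparisons", {
  # reversed indicator: low turnout is the risk signal
  expect_true(evaluate_indicator(indicator_defn("voter_turnout"), 30))
  expect_false(evaluate_indicator(indicator_defn("voter_turnout"), 35))
  expect_false(evaluate_indicator(indicator_defn("voter_turnout"), 40))
  # boundary value with strict inequality never flags
  expect_false(evaluate_indicator(indicator_defn("violent_crime"), 300))
  expect_true(evaluate_indicator(indicator_defn("violent_crime"), 300.1))
  # booleans flag on presence
  expect_true(evaluate_indicator(indicator_defn("hidta"), TRUE))
  expect_false(evaluate_indicator(indicator_defn("hidta"), FALSE))
  # counts compare like rates
  expect_true(evaluate_indicator(indicator_defn("veterans"), 2500))
  # protective-looking directions are implemented as printed: exceedance flags
  expect_true(evaluate_indicator(indicator_defn("median_income"), 60000))
  expect_true(evaluate_indicator(indicator_defn("college_degree"), 45))
})

test_that("evaluate_indicator rejects missing and invalid measurements", {
  expect_error(evaluate_indicator(indicator_defn("hs_dropout"), NA),
               class = "castr_missing_data_error")
  expect_error(evaluate_indicator(indicator_defn("hs_dropout"), -1),
               class = "castr_domain_error")
  expect_error(evaluate_indicator(indicator_defn("hidta"), 3),
               class = "castr_domain_error")
})

test_that("tally_flags counts per group and honours the missing policy", {
  counts <- tally_flags(flagged_profile(0, 0))
  expect_equal(counts, list(k_social = 0L, n_social = 11L,
                            k_community = 0L, n_community = 7L))
  counts <- tally_flags(flagged_profile(11, 7))
  expect_equal(counts, list(k_social = 11L, n_social = 11L,
                            k_community = 7L, n_community = 7L))

  # two unmeasured social indicators shrink the denominator under exclude
  p <- flagged_profile(5, 2)
  drop <- head(p$measurements$indicator_id[
    p$measurements$indicator_id %in%
      default_indicators()$id[default_indicators()$group == "social"]], 2)
  p$measurements$value[p$measurements$indicator_id %in% drop] <- list(NA, NA)
  expect_warning(counts <- tally_flags(p), "excluded 2")
  expect_equal(counts$n_social, 9L)
  expect_equal(counts$n_community, 7L)
  expect_error(suppressWarnings(tally_flags(p, missing_policy = "error")),
               class = "castr_missing_data_error")

  p$measurements$indicator_id[1] <- "no_such_indicator"
  expect_error(suppressWarnings(tally_flags(p)),
               class = "castr_unknown_indicator_error")
})

test_that("prevalence_ratio is k/n with guarded edge cases", {
  expect_equal(prevalence_ratio(0, 11), 0)
  expect_equal(prevalence_ratio(7, 11), 7 / 11)
  expect_equal(prevalence_ratio(11, 11), 1)
  expect_warning(r0 <- prevalence_ratio(0, 0), "no evaluable")
  expect_equal(r0, 0)
  expect_error(prevalence_ratio(3, 2), class = "castr_inconsistency_error")
})

test_that("risk multiplier reproduces the published risk scores", {
  expect_equal(risk_multiplier(7 / 11, 1 / 7)$score, 0.78)
  expect_equal(risk_multiplier(7 / 11, 3 / 7)$score, 1.06)
  expect_equal(risk_multiplier(7 / 11, 1 / 7)$multiplier, 60 / 77)
  expect_equal(risk_multiplier(0, 0, mode = "equation")$multiplier, 1)
  expect_error(risk_multiplier(1.2, 0), class = "castr_domain_error")
})

test_that("multiplier over the full flag grid matches the closed form", {
  # brute-force oracle through the full tally -> ratio -> multiplier path
  for (ks in c(0L, 3L, 7L, 11L)) {
    for (kc in 0:7) {
      risk <- assess_risk(flagged_profile(ks, kc, seed = 7))
      expect_equal(risk$multiplier, ks / 11 + kc / 7, tolerance = 1e-12)
      eqn <- risk_multiplier(ks / 11, kc / 7, mode = "equation")
      expect_equal(eqn$multiplier, risk$multiplier + 1, tolerance = 1e-12)
    }
  }
})

test_that("multiplier is monotone in flag counts and permutation-invariant", {
  grid <- expand.grid(ks = 0:11, kc = 0:7)
  m <- with(grid, ks / 11 + kc / 7)
  for (i in seq_len(nrow(grid))) {
    up_s <- which(grid$ks == grid$ks[i] + 1 & grid$kc == grid$kc[i])
    up_c <- which(grid$ks == grid$ks[i] & grid$kc == grid$kc[i] + 1)
    if (length(up_s)) expect_gte(m[up_s], m[i])
    if (length(up_c)) expect_gte(m[up_c], m[i])
  }
  # which indicators flag does not matter, only how many per group
  m1 <- assess_risk(flagged_profile(6, 4, seed = 1))$multiplier
  m2 <- assess_risk(flagged_profile(6, 4, seed = 999))$multiplier
  expect_identical(m1, m2)
})
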