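test_that("maximum need is (X1 * Y1) / Z1 with guarded parameters", {
  expect_equal(max_component_need(1200, 1, 1), 1200)
  expect_equal(max_component_need(1000, 12, 10), 1200)
  expect_equal(max_component_need(0, 52, 8), 0)
  expect_error(max_component_need(100, 1, 0.5), class = "castr_domain_error")
  expect_error(max_component_need(100, 0, 5), class = "castr_domain_error")
  expect_error(max_component_need(-1, 1, 5), class = "castr_domain_error")
})

test_that("adjusted need reproduces printed worked-example rows", {
  # base needs inverted from community A under its displayed 0.78 score
  expect_equal(adjusted_need(106 / 0.78, 1.06, 1), 144)
  expect_equal(adjusted_need(35 / 0.78, 1.06, 1), 48)
  expect_equal(adjusted_need(10, 1, 0), 0)
  expect_equal(adjusted_need(2.5, 1, 1), 3)          # half rounds up
  expect_equal(adjusted_need(2.5, 1, 1, rounding = "ceiling"), 3)
  expect_equal(adjusted_need(2.1, 1, 1, rounding = "ceiling"), 3)
  expect_error(adjusted_need(-1, 1, 1), class = "castr_domain_error")
  expect_error(adjusted_need(1, 1, 1.4), class = "castr_domain_error")
})

test_that("pre-rounding need scales linearly in X1, Y1, U and inversely in Z1", {
  base <- max_component_need(3500, 12, 20) * 0.9 * 0.4
  expect_equal(max_component_need(7000, 12, 20) * 0.9 * 0.4, 2 * base)
  expect_equal(max_component_need(3500, 24, 20) * 0.9 * 0.4, 2 * base)
  expect_equal(max_component_need(3500, 12, 40) * 0.9 * 0.4, base / 2)
  expect_equal(max_component_need(3500, 12, 20) * 0.9 * 0.8, 2 * base)
  # multiplier and usage rate commute exactly
  expect_identical(adjusted_need(137.3, 0.78, 0.4),
                   adjusted_need(137.3, 0.4, 0.78))
})

test_that("assess_community yields one estimate per component under one multiplier", {
  p <- flagged_profile(7, 1)
  report <- assess_community(p)
  expect_s3_class(report, "cast_report")
  expect_equal(nrow(report), 32)
  expect_equal(report$component_id, default_components()$id)
  risk <- attr(report, "risk")
  expect_equal(risk$score, 0.78)
  expect_equal(report$adjusted_need_raw,
               report$max_need * risk$multiplier *
                 default_components()$usage_rate)
  expect_true(all(report$recommended_units >= 0))
  prov <- attr(report, "provenance")
  expect_equal(prov$mode, "score")
  expect_match(prov$component_checksum, "^[0-9a-f]{32}$")
})

test_that("riskier communities never need fewer units, empty ones need none", {
  lo <- assess_community(flagged_profile(2, 1, seed = 3))
  hi <- assess_community(flagged_profile(9, 5, seed = 3))
  expect_true(all(hi$recommended_units >= lo$recommended_units))

  ghost <- generate_profile(5, 4, 2, population = 0)
  expect_true(all(assess_community(ghost)$recommended_units == 0))
})

test_that("category subtotals conserve the overall total", {
  report <- assess_community(flagged_profile(7, 3))
  summ <- category_summary(report)
  expect_equal(nrow(summ), 6)
  expect_equal(summ$recommended_units[summ$category == "total"],
               sum(report$recommended_units))
  expect_equal(sum(summ$recommended_units[summ$category != "total"]),
               sum(report$recommended_units))
  expect_equal(sum(summ$n_components[summ$category != "total"]), 32L)
})

test_that("gap analysis reports signed shortfalls and redundancies", {
  report <- assess_community(flagged_profile(7, 1))
  inv <- tibble::tibble(component_id = c("twelve_step", "transportation"),
                        observed_units = c(100L, 500L))
  gapped <- gap_analysis(report, inv)
  expect_equal(nrow(gapped), 32)
  ts <- gapped[gapped$component_id == "twelve_step", ]
  expect_equal(ts$gap, ts$recommended_units - 100L)
  tr <- gapped[gapped$component_id == "transportation", ]
  expect_true(tr$gap < 0)  # redundancy stays negative
  unreported <- gapped[!gapped$reported, ]
  expect_equal(unreported$observed_units, rep(0L, nrow(unreported)))
  expect_equal(unreported$gap, unreported$recommended_units)

  empty <- tibble::tibble(component_id = character(),
                          observed_units = integer())
  expect_equal(gap_analysis(report, empty)$gap, report$recommended_units)
  expect_error(
    gap_analysis(report, tibble::tibble(component_id = "bogus",
                                        observed_units = 1L)),
    class = "castr_unknown_component_error")
})

test_that("Monte Carlo sensitivity is seeded, degenerate at zero noise", {
  p <- flagged_profile(7, 1)
  s0 <- sensitivity_mc(p, perturbation_scale = 0, replications = 25, seed = 9)
  expect_equal(s0$low, s0$point)
  expect_equal(s0$high, s0$point)

  s1 <- sensitivity_mc(p, perturbation_scale = 0.1, replications = 100,
                       seed = 11)
  s2 <- sensitivity_mc(p, perturbation_scale = 0.1, replications = 100,
                       seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1$low <= s1$point & s1$point <= s1$high))
  expect_error(sensitivity_mc(p, replications = 0),
               class = "castr_domain_error")
})

test_that("wider perturbation widens the intervals", {
  p <- flagged_profile(7, 3)
  narrow <- sensitivity_mc(p, perturbation_scale = 0.05, replications = 400,
                           seed = 2)
  wide <- sensitivity_mc(p, perturbation_scale = 0.2, replications = 400,
                         seed = 2)
  expect_gt(mean(wide$high - wide$low), mean(narrow$high - narrow$low))
})

test_that("sensitivity_mc leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(sensitivity_mc(flagged_profile(1, 1), replications = 5))
  expect_identical(.Random.seed, before)
})
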