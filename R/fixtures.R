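#' Printed unit counts of the published two-community worked example
#'
#' The 32 pairs of adjusted community need (recommended units) printed for
#' two hypothetical communities of 50,000 with displayed risk scores 0.78
#' and 1.06. These anchor the package's reconstruction tests.
#'
#' @return a tibble: `component_id, value_a, value_b`.
#' @export
worked_example_pairs <- function() {
  ids <- default_components()$id
  a <- c(20, 7, 1,
         54, 48, 4, 1, 27, 1, 9,
         7, 2, 3, 0, 1, 17,
         11, 35, 13, 21, 11, 20, 1,
         1, 106, 64, 154, 3, 32, 14, 1, 10)
  b <- c(27, 10, 2,
         74, 66, 6, 1, 36, 2, 13,
         9, 2, 4, 0, 1, 24,
         14, 48, 17, 29, 14, 27, 1,
         1, 144, 86, 210, 4, 43, 19, 2, 13)
  tibble::tibble(component_id = ids,
                 value_a = as.integer(a), value_b = as.integer(b))
}

#' Feasible base-need interval for a printed pair of recommendations
#'
#' Inverts the final rounding step: the set of real base needs `B >= 0`
#' such that `half_up(m_a * B) = value_a` and `half_up(m_b * B) = value_b`
#' simultaneously, computed by intersecting the two half-open rounding
#' preimages `[(v - 0.5) / m, (v + 0.5) / m)`. A non-empty interval proves
#' the printed pair is jointly consistent with a single unprinted base
#' need under the two multipliers.
#'
#' @param value_a,value_b printed integer unit counts for the two
#'   communities.
#' @param m_a,m_b the two risk multipliers (`> 0`).
#' @return a list with `low`, `high` (the half-open interval
#'   `[low, high)`), and `empty`.
#' @export
#' @examples
#' feasible_base_interval(106, 144, 0.78, 1.06)  # ~[135.38, 136.32)
feasible_base_interval <- function(value_a, value_b, m_a, m_b) {
  check_count(value_a, "value_a"); check_count(value_b, "value_b")
  if (m_a <= 0 || m_b <= 0) stop_domain("multipliers must be > 0.")
  low <- max(max(value_a - 0.5, 0) / m_a, max(value_b - 0.5, 0) / m_b)
  high <- min((value_a + 0.5) / m_a, (value_b + 0.5) / m_b)
  list(low = low, high = high, empty = !(high > low))
}

# Demographic composition shared by all synthetic profiles: roughly
# national age structure and a 10% substance-use prevalence among ages
# 12-65 (a plausible subregional survey estimate).
synthetic_demographics <- function() {
  list(pct_age_10_19 = 0.13, pct_age_20_65 = 0.60, pct_age_12_65 = 0.70,
       pct_male = 0.49, substance_use_prevalence = 0.10)
}

#' Generate a synthetic community profile with controlled risk structure
#'
#' Draws indicator values uniformly from plausible ranges strictly above or
#' below each threshold so that exactly `k_social` of the 11 social and
#' `k_community` of the 7 community indicators flag. Which indicators flag
#' is itself randomised; boolean indicators flag by being TRUE. Fully
#' reproducible under a fixed seed; the caller's RNG state is preserved.
#'
#' @param seed RNG seed.
#' @param k_social,k_community requested flag counts (0-11 and 0-7 with the
#'   default registry).
#' @param population total population (default 50,000, the worked example's
#'   shared size).
#' @param name profile label.
#' @param registry indicator registry to draw against.
#' @return a [community_profile()] with all indicators measured.
#' @export
#' @examples
#' p <- generate_profile(1, k_social = 7, k_community = 1)
#' assess_risk(p)$score  # 0.78
generate_profile <- function(seed, k_social, k_community,
                             population = 50000,
                             name = sprintf("synthetic-%d-%d-%d",
                                            seed, k_social, k_community),
                             registry = default_indicators()) {
  n_social <- sum(registry$group == "social")
  n_community <- sum(registry$group == "community")
  check_count(k_social, "k_social")
  check_count(k_community, "k_community")
  if (k_social > n_social || k_community > n_community) {
    stop_domain(sprintf(
      "requested flag counts exceed registry sizes (%d social, %d community).",
      n_social, n_community))
  }
  with_preserved_rng(seed, {
    flagged <- logical(nrow(registry))
    for (grp in c("social", "community")) {
      idx <- which(registry$group == grp)
      k <- if (grp == "social") k_social else k_community
      flagged[sample(idx, k)] <- TRUE
    }
    value <- vector("list", nrow(registry))
    for (i in seq_len(nrow(registry))) {
      kind <- registry$kind[i]
      t <- registry$threshold[i]
      value[[i]] <- if (kind == "boolean") {
        flagged[i]
      } else if (kind == "rate_below") {
        if (flagged[i]) t * runif(1, 0.5, 0.95) else t * runif(1, 1.05, 1.5)
      } else {
        if (flagged[i]) t * runif(1, 1.05, 1.5) else t * runif(1, 0.5, 0.95)
      }
    }
    demo <- synthetic_demographics()
    community_profile(
      name = name, total_population = population,
      pct_age_10_19 = demo$pct_age_10_19,
      pct_age_20_65 = demo$pct_age_20_65,
      pct_age_12_65 = demo$pct_age_12_65,
      pct_male = demo$pct_male,
      substance_use_prevalence = demo$substance_use_prevalence,
      measurements = tibble::tibble(indicator_id = registry$id, value = value)
    )
  })
}

#' Reconstruct the published two-community worked example
#'
#' Builds a fully specified fixture that reproduces the worked example's 64
#' printed unit counts: two synthetic profiles of 50,000 flagging exactly
#' 7/11 social + 1/7 community indicators (displayed risk score 0.78) and
#' 7/11 + 3/7 (score 1.06) — the unique flag-count decompositions of the
#' printed scores — plus a component parameter table whose base needs are
#' the midpoints of each pair's feasible interval under the two displayed
#' scores, back-solved into `dosage_frequency` with unit group size and
#' usage rate.
#'
#' Reproducing the printed counts requires applying the displayed
#' (2-decimal) risk scores as multipliers, so assessments of this fixture
#' must use `multiplier_digits = 2` (see the methods vignette). Any empty
#' feasible interval aborts: the error doubles as a validation of the
#' reconstruction.
#'
#' @return a list: `profile_a`, `profile_b` (community profiles),
#'   `components` (back-solved parameter registry), `base_needs` (named
#'   vector of interval midpoints), `pairs` ([worked_example_pairs()]),
#'   `multiplier_a`, `multiplier_b` (0.78, 1.06).
#' @export
#' @examples
#' wx <- worked_example()
#' rep_a <- assess_community(wx$profile_a, component_registry = wx$components,
#'                           multiplier_digits = 2)
#' all(rep_a$recommended_units == wx$pairs$value_a)
worked_example <- function() {
  pairs <- worked_example_pairs()
  m_a <- 0.78
  m_b <- 1.06
  intervals <- lapply(seq_len(nrow(pairs)), function(i) {
    feasible_base_interval(pairs$value_a[i], pairs$value_b[i], m_a, m_b)
  })
  empty <- vapply(intervals, `[[`, logical(1), "empty")
  if (any(empty)) {
    abort(sprintf("worked-example reconstruction failed: empty interval for %s",
                  paste(pairs$component_id[empty], collapse = ", ")),
          class = "castr_fixture_inconsistency_error")
  }
  base_needs <- vapply(intervals, function(iv) (iv$low + iv$high) / 2,
                       numeric(1))
  names(base_needs) <- pairs$component_id
  population <- 50000
  components <- default_components()
  components$selector_base <- "total_population"
  components$selector_fraction <- 1
  components$group_size <- 1
  components$usage_rate <- 1
  components$dosage_frequency <- base_needs / population
  validate_component_registry(components)
  list(
    profile_a = generate_profile(101, k_social = 7, k_community = 1,
                                 population = population,
                                 name = "community-A"),
    profile_b = generate_profile(102, k_social = 7, k_community = 3,
                                 population = population,
                                 name = "community-B"),
    components = components,
    base_needs = base_needs,
    pairs = pairs,
    multiplier_a = m_a,
    multiplier_b = m_b
  )
}
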