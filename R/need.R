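#' Maximum community need for a component
#'
#' Units required for 100% coverage of the target population before risk and
#' usage adjustment: `(X1 * Y1) / Z1`, in exact real arithmetic.
#'
#' @param x1 target population (persons, `>= 0`).
#' @param dosage_frequency Y1, events per person-year (`> 0`).
#' @param group_size Z1, participants served per unit (`>= 1`).
#' @return real-valued unit count.
#' @export
#' @examples
#' max_component_need(1000, 12, 10)  # 1200
max_component_need <- function(x1, dosage_frequency, group_size) {
  check_nonneg(x1, "x1")
  if (!is.numeric(dosage_frequency) || any(dosage_frequency <= 0)) {
    stop_domain("`dosage_frequency` must be > 0.")
  }
  if (!is.numeric(group_size) || any(group_size < 1)) {
    stop_domain("`group_size` must be >= 1.")
  }
  (x1 * dosage_frequency) / group_size
}

#' Risk- and usage-adjusted recommended units
#'
#' Multiplies maximum need by the community risk multiplier and the
#' component's usage rate, then rounds once, at the end, to an integer unit
#' count. Because the three factors commute, the order in which the risk
#' adjustment and usage rate are applied is immaterial. `half_up` (default)
#' rounds 0.5 up; `ceiling` never under-provisions and suits conservative
#' capacity planning.
#'
#' @param max_need real-valued maximum need (`>= 0`).
#' @param multiplier community risk multiplier (`>= 0`).
#' @param usage_rate U, in `[0, 1]`.
#' @param rounding `"half_up"` (default) or `"ceiling"`.
#' @return non-negative integer unit count.
#' @export
#' @examples
#' adjusted_need(106 / 0.78, 1.06, 1)  # 144
adjusted_need <- function(max_need, multiplier, usage_rate,
                          rounding = c("half_up", "ceiling")) {
  check_nonneg(max_need, "max_need")
  check_nonneg(multiplier, "multiplier")
  check_proportion(usage_rate, "usage_rate")
  apply_rounding(max_need * multiplier * usage_rate, rounding)
}

registry_checksum <- function(registry) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(registry, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Assess a community's care-system needs
#'
#' Runs the full CAST pipeline: scores the profile against the indicator
#' registry, resolves each component's target population, applies the need
#' equation `(X1 * Y1) / Z1 * multiplier * U`, and rounds to recommended
#' integer units. A single community-wide multiplier is applied to every
#' component.
#'
#' By default the full-precision multiplier flows through the computation
#' and the 2-decimal risk score is display-only. Setting
#' `multiplier_digits = 2` instead applies the displayed score itself, which
#' is how the published worked example's unit counts were produced (see the
#' methods vignette).
#'
#' @param profile a [community_profile()].
#' @param indicator_registry indicator definitions; default shipped registry.
#' @param component_registry component parameters; default shipped registry.
#' @param mode risk-multiplier mode, `"score"` or `"equation"`.
#' @param rounding `"half_up"` or `"ceiling"`.
#' @param missing_policy `"exclude"` or `"error"` for unmeasured indicators.
#' @param multiplier_digits optional number of decimals to round the
#'   multiplier to before applying it; `NULL` (default) = full precision.
#' @return a `cast_report`: a tibble with one row per component
#'   (`component_id, category, name, unit_label, x1, max_need,
#'   adjusted_need_raw, recommended_units`), carrying the `cast_risk`
#'   object and a provenance list as attributes.
#' @seealso [gap_analysis()], [sensitivity_mc()], [write_report()]
#' @export
assess_community <- function(profile,
                             indicator_registry = default_indicators(),
                             component_registry = default_components(),
                             mode = c("score", "equation"),
                             rounding = c("half_up", "ceiling"),
                             missing_policy = c("exclude", "error"),
                             multiplier_digits = NULL) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  validate_component_registry(component_registry)
  risk <- assess_risk(profile, indicator_registry, mode, missing_policy)
  multiplier <- risk$multiplier
  if (!is.null(multiplier_digits)) {
    multiplier <- round(multiplier, multiplier_digits)
  }
  x1 <- vapply(seq_len(nrow(component_registry)), function(i) {
    resolve_target_population(profile,
                              component_registry$selector_base[i],
                              component_registry$selector_fraction[i])
  }, numeric(1))
  max_need <- max_component_need(x1, component_registry$dosage_frequency,
                                 component_registry$group_size)
  raw <- max_need * multiplier * component_registry$usage_rate
  rows <- tibble::tibble(
    component_id = component_registry$id,
    category = component_registry$category,
    name = component_registry$name,
    unit_label = component_registry$unit_label,
    x1 = x1,
    max_need = max_need,
    adjusted_need_raw = raw,
    recommended_units = as.integer(apply_rounding(raw, rounding))
  )
  provenance <- list(
    community = profile$name,
    mode = mode,
    rounding = rounding,
    multiplier = multiplier,
    risk_score = risk$score,
    multiplier_digits = multiplier_digits,
    component_checksum = registry_checksum(component_registry),
    indicator_checksum = registry_checksum(indicator_registry)
  )
  structure(rows, class = c("cast_report", class(rows)),
            risk = risk, provenance = provenance)
}

#' @export
print.cast_report <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<cast_report> %s: %d components, risk score %.2f (mode %s)\n",
              prov$community, nrow(x), prov$risk_score, prov$mode))
  NextMethod()
}

#' Per-category summary of a need/gap report
#'
#' @param report a `cast_report`.
#' @return a tibble with per-category component counts and summed
#'   recommended units (plus observed units and gaps when present), followed
#'   by an overall `total` row.
#' @export
category_summary <- function(report) {
  cats <- unique(report$category)
  has_gap <- "gap" %in% names(report)
  one <- function(rows, label) {
    out <- tibble::tibble(category = label,
                          n_components = nrow(rows),
                          recommended_units = sum(rows$recommended_units))
    if (has_gap) {
      out$observed_units <- sum(rows$observed_units)
      out$gap <- sum(rows$gap)
    }
    out
  }
  per <- lapply(cats, function(cc) one(report[report$category == cc, ], cc))
  do.call(rbind, c(per, list(one(report, "total"))))
}

#' Read observed component inventory from CSV
#'
#' @param path CSV with header `component_id,observed_units`.
#' @return tibble of inventory records with non-negative integer units.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("inventory file not found: %s", path))
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component_id", "observed_units") %in% names(tab))) {
    stop_validation("inventory needs header columns `component_id,observed_units`.")
  }
  units <- suppressWarnings(as.numeric(tab$observed_units))
  bad <- which(is.na(units) | units < 0 | units != trunc(units))
  if (length(bad)) {
    stop_validation(sprintf(
      "inventory row(s) %s: observed_units must be non-negative integers.",
      paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tab$component_id)) {
    stop_validation("inventory has duplicate component ids.")
  }
  tibble::tibble(component_id = as.character(tab$component_id),
                 observed_units = as.integer(units))
}

#' Gap analysis: recommended minus observed units
#'
#' Positive gaps are shortfalls, negative gaps redundancies (kept signed,
#' not truncated at zero). Components absent from the inventory are treated
#' as observed 0 and marked unreported.
#'
#' @param report a `cast_report` from [assess_community()].
#' @param inventory inventory records from [read_inventory()], or a data
#'   frame with `component_id` and `observed_units`.
#' @return the report with `observed_units`, `gap`, and `reported` columns.
#' @export
gap_analysis <- function(report, inventory) {
  unknown <- setdiff(inventory$component_id, report$component_id)
  if (length(unknown)) {
    abort(sprintf("inventory has unknown component id(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "castr_unknown_component_error")
  }
  j <- match(report$component_id, inventory$component_id)
  report$observed_units <- ifelse(is.na(j), 0L,
                                  as.integer(inventory$observed_units[j]))
  report$reported <- !is.na(j)
  report$gap <- report$recommended_units - report$observed_units
  report
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Monte Carlo sensitivity of the recommendations
#'
#' Each replication independently perturbs every component's Y1, Z1, and U
#' with multiplicative lognormal noise of relative scale
#' `perturbation_scale` (clamped back to valid ranges: Z1 >= 1, U in
#' `[0, 1]`), recomputes all recommendations, and empirical percentile
#' intervals are taken per component. Optionally the indicator thresholds
#' are perturbed the same way and the risk score re-derived per
#' replication. Identical seeds give identical results; zero scale
#' collapses every interval to the point recommendation.
#'
#' @inheritParams assess_community
#' @param perturbation_scale relative standard deviation of the lognormal
#'   noise (`>= 0`).
#' @param replications number of Monte Carlo replications (`>= 1`).
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param level interval coverage level, default 0.95.
#' @param perturb_thresholds also perturb indicator thresholds and
#'   re-derive the risk multiplier each replication (default `FALSE`).
#' @return a `cast_sensitivity` tibble: `component_id, point, low, high`,
#'   with replication settings as attributes.
#' @export
sensitivity_mc <- function(profile,
                           indicator_registry = default_indicators(),
                           component_registry = default_components(),
                           perturbation_scale = 0.1,
                           replications = 1000,
                           seed = 1L,
                           level = 0.95,
                           mode = c("score", "equation"),
                           rounding = c("half_up", "ceiling"),
                           perturb_thresholds = FALSE) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  check_nonneg(perturbation_scale, "perturbation_scale")
  check_count(replications, "replications", min = 1L)
  check_proportion(level, "level")
  validate_component_registry(component_registry)
  base <- assess_community(profile, indicator_registry, component_registry,
                           mode, rounding)
  risk <- attr(base, "risk")
  n_comp <- nrow(component_registry)
  x1 <- base$x1
  draws <- with_preserved_rng(seed, {
    out <- matrix(0L, nrow = replications, ncol = n_comp)
    for (r in seq_len(replications)) {
      noise <- function(n) rlnorm(n, meanlog = 0, sdlog = perturbation_scale)
      y1 <- component_registry$dosage_frequency * noise(n_comp)
      z1 <- pmax(component_registry$group_size * noise(n_comp), 1)
      u <- pmin(component_registry$usage_rate * noise(n_comp), 1)
      mult <- risk$multiplier
      if (perturb_thresholds) {
        reg <- indicator_registry
        nb <- reg$kind != "boolean"
        reg$threshold[nb] <- reg$threshold[nb] * noise(sum(nb))
        mult <- assess_risk(profile, reg, mode)$multiplier
      }
      out[r, ] <- as.integer(apply_rounding(x1 * y1 / z1 * mult * u, rounding))
    }
    out
  })
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, probs = c(alpha, 1 - alpha), type = 1,
              names = FALSE)
  res <- tibble::tibble(
    component_id = component_registry$id,
    point = base$recommended_units,
    low = as.integer(qs[1, ]),
    high = as.integer(qs[2, ])
  )
  structure(res, class = c("cast_sensitivity", class(res)),
            replications = replications,
            perturbation_scale = perturbation_scale,
            seed = seed, level = level,
            perturb_thresholds = perturb_thresholds)
}

#' @export
print.cast_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<cast_sensitivity> %d replications, scale %.3g, %.0f%% intervals\n",
    attr(x, "replications"), attr(x, "perturbation_scale"),
    100 * attr(x, "level")))
  NextMethod()
}
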