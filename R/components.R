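cast_categories <- c("promotion", "prevention", "referral", "treatment",
                     "recovery")
selector_bases <- c("total_population", "age_10_19", "age_20_65",
                    "age_12_65", "substance_users")

#' Default registry of the 32 care-system components
#'
#' The continuum-of-care framework: 32 components partitioned over the five
#' categories as promotion 3, prevention 7, referral 6, treatment 7,
#' recovery 9. Each component carries its need parameters:
#' `dosage_frequency` (Y1, events per person-year), `group_size` (Z1,
#' participants served per unit), `usage_rate` (U, proportion of the
#' eligible population expected to use the component), and a target
#' population selector (`selector_base`, `selector_fraction`) defining X1.
#'
#' The component list and unit labels are the published framework; the
#' shipped parameter values are documented synthetic placeholders (the
#' published calculator's per-component values are not public), intended to
#' be overridden with locally sourced values via `overrides` or a user file.
#'
#' @param path optional path to a parameter CSV with the columns named
#'   above plus `id, category, name, unit_label`; defaults to the shipped
#'   placeholder table.
#' @param overrides optional data frame of field-wise overrides keyed by
#'   `id`: non-`NA` entries replace the registry values.
#' @return a validated tibble with 32 rows (one per component).
#' @export
#' @examples
#' reg <- default_components()
#' table(reg$category)
#' tweaked <- default_components(overrides = data.frame(
#'   id = "twelve_step", usage_rate = 0.5))
default_components <- function(path = NULL, overrides = NULL) {
  path <- path %||% system.file("extdata", "components_synthetic_defaults.csv",
                                package = "castr")
  reg <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(overrides)) {
    if (!"id" %in% names(overrides)) {
      stop_validation("`overrides` needs an `id` column.")
    }
    unknown <- setdiff(overrides$id, reg$id)
    if (length(unknown)) {
      abort(sprintf("override(s) for unknown component id(s): %s",
                    paste(unknown, collapse = ", ")),
            class = "castr_unknown_component_error")
    }
    fields <- intersect(names(overrides), setdiff(names(reg), "id"))
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$id[i], reg$id)
      for (f in fields) {
        v <- overrides[[f]][i]
        if (!is.na(v)) reg[[f]][j] <- v
      }
    }
  }
  validate_component_registry(reg)
  reg
}

validate_component_registry <- function(registry) {
  required <- c("id", "category", "name", "unit_label", "selector_base",
                "selector_fraction", "dosage_frequency", "group_size",
                "usage_rate")
  missing <- setdiff(required, names(registry))
  if (length(missing)) {
    stop_validation(sprintf("component registry lacks columns: %s",
                            paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(registry$id)) {
    stop_validation("component registry has duplicate ids.")
  }
  bad <- character()
  if (!all(registry$category %in% cast_categories)) bad <- c(bad, "category")
  if (!all(registry$selector_base %in% selector_bases)) {
    bad <- c(bad, "selector_base")
  }
  if (any(is.na(registry$selector_fraction) | registry$selector_fraction < 0 |
          registry$selector_fraction > 1)) {
    bad <- c(bad, "selector_fraction")
  }
  if (any(is.na(registry$dosage_frequency) | registry$dosage_frequency <= 0)) {
    bad <- c(bad, "dosage_frequency")
  }
  if (any(is.na(registry$group_size) | registry$group_size < 1)) {
    bad <- c(bad, "group_size")
  }
  if (any(is.na(registry$usage_rate) | registry$usage_rate < 0 |
          registry$usage_rate > 1)) {
    bad <- c(bad, "usage_rate")
  }
  if (length(bad)) {
    stop_validation(sprintf("component registry field(s) violate invariants: %s",
                            paste(bad, collapse = ", ")))
  }
  invisible(registry)
}

#' Resolve a component's target population (X1)
#'
#' X1 = total population x base proportion x selector fraction. The
#' `substance_users` base is the population aged 12-65 multiplied by the
#' profile's expected substance-use prevalence; `selector_fraction` narrows
#' further (e.g. the employed share for workplace programs). Values are
#' real-valued at this stage; rounding happens only on the final
#' recommendation.
#'
#' @param profile a [community_profile()].
#' @param selector_base one of `"total_population"`, `"age_10_19"`,
#'   `"age_20_65"`, `"age_12_65"`, `"substance_users"`.
#' @param selector_fraction additional proportion of the base, in `[0, 1]`.
#' @return persons (non-negative real).
#' @export
#' @examples
#' p <- community_profile("demo", 50000, pct_age_12_65 = 0.7,
#'                        substance_use_prevalence = 0.1)
#' resolve_target_population(p, "substance_users")  # 3500
resolve_target_population <- function(profile, selector_base,
                                      selector_fraction = 1) {
  if (!selector_base %in% selector_bases) {
    stop_validation(sprintf("unknown selector base '%s'.", selector_base))
  }
  check_proportion(selector_fraction, "selector_fraction")
  need_prop <- function(field) {
    v <- profile[[field]]
    if (is.null(v) || is.na(v)) {
      abort(sprintf("selector '%s' needs profile field `%s`, which is unset.",
                    selector_base, field),
            class = "castr_missing_demographic_error")
    }
    v
  }
  base_prop <- switch(selector_base,
    total_population = 1,
    age_10_19 = need_prop("pct_age_10_19"),
    age_20_65 = need_prop("pct_age_20_65"),
    age_12_65 = need_prop("pct_age_12_65"),
    substance_users =
      need_prop("pct_age_12_65") * need_prop("substance_use_prevalence")
  )
  profile$total_population * base_prop * selector_fraction
}
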