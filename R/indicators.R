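#' Default registry of social and community risk indicators
#'
#' Returns the 18 county-level indicators (11 social, 7 community) used to
#' score a community's substance-abuse risk, with their published thresholds.
#' Rate/count indicators flag on a strict comparison with the threshold in
#' the indicator's native units; boolean indicators flag when present.
#' Demographics (age structure, sex, total population) are community-profile
#' fields, not indicators, and never flag.
#'
#' Three indicators (median household income above $53,000, college-degree
#' share above 30%, exercise access above 50%) flag on exceedance exactly as
#' published, even though their direction can look protective.
#'
#' @param path optional path to a registry CSV with columns
#'   `id, group, kind, threshold, units, description, source_note`;
#'   defaults to the registry shipped with the package.
#' @return a tibble with one row per indicator definition.
#' @seealso [evaluate_indicator()], [tally_flags()], [assess_risk()]
#' @export
#' @examples
#' reg <- default_indicators()
#' table(reg$group)
default_indicators <- function(path = NULL) {
  path <- path %||% system.file("extdata", "indicators.csv", package = "castr")
  reg <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  reg$threshold <- as.numeric(reg$threshold)
  validate_indicator_registry(reg)
  reg
}

validate_indicator_registry <- function(registry) {
  required <- c("id", "group", "kind", "threshold", "units", "description")
  missing <- setdiff(required, names(registry))
  if (length(missing)) {
    stop_validation(sprintf("indicator registry lacks columns: %s",
                            paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(registry$id)) {
    stop_validation("indicator registry has duplicate ids.")
  }
  if (!all(registry$group %in% c("social", "community"))) {
    stop_validation("indicator `group` must be 'social' or 'community'.")
  }
  kinds <- c("rate_above", "rate_below", "count_above", "boolean")
  if (!all(registry$kind %in% kinds)) {
    stop_validation(sprintf("indicator `kind` must be one of: %s",
                            paste(kinds, collapse = ", ")))
  }
  bool <- registry$kind == "boolean"
  if (any(!is.na(registry$threshold[bool]))) {
    stop_validation("boolean indicators must not carry a threshold.")
  }
  if (any(is.na(registry$threshold[!bool]))) {
    stop_validation("rate/count indicators must carry a numeric threshold.")
  }
  invisible(registry)
}

#' Evaluate one indicator measurement against its definition
#'
#' Flags use strict inequalities, matching the published threshold wording:
#' `rate_above`/`count_above` flag when the value strictly exceeds the
#' threshold, `rate_below` when strictly under it, `boolean` flags on TRUE.
#' A value exactly at the threshold never flags.
#'
#' @param defn one-row indicator definition (a row of [default_indicators()]).
#' @param value the measured value in the definition's native units
#'   (logical for boolean indicators), or `NA` for missing.
#' @return `TRUE` if the indicator flags, `FALSE` otherwise.
#' @export
#' @examples
#' reg <- default_indicators()
#' evaluate_indicator(reg[reg$id == "voter_turnout", ], 30)  # <35% flags
evaluate_indicator <- function(defn, value) {
  if (is.data.frame(defn) && nrow(defn) != 1L) {
    stop_validation("`defn` must be a single indicator definition row.")
  }
  if (length(value) != 1L || is.na(value)) {
    abort(sprintf("measurement for indicator '%s' is missing.", defn$id),
          class = "castr_missing_data_error")
  }
  if (defn$kind == "boolean") {
    if (!is.logical(value) && !value %in% c(0, 1)) {
      stop_domain(sprintf("boolean indicator '%s' needs a TRUE/FALSE value.",
                          defn$id))
    }
    return(as.logical(value))
  }
  if (!is.numeric(value) || value < 0) {
    stop_domain(sprintf("indicator '%s' needs a non-negative numeric value.",
                        defn$id))
  }
  switch(defn$kind,
    rate_above  = value > defn$threshold,
    count_above = value > defn$threshold,
    rate_below  = value < defn$threshold
  )
}

#' Tally flagged indicators by group
#'
#' Evaluates every registered indicator against a community profile's
#' measurements and counts flags per group. Under the default
#' `missing_policy = "exclude"`, indicators without a measurement are
#' dropped from both numerator and denominator (with a warning);
#' `"error"` aborts instead, for strict runs.
#'
#' @param profile a [community_profile()].
#' @param registry an indicator registry tibble; defaults to the shipped one.
#' @param missing_policy `"exclude"` (default) or `"error"`.
#' @return a list with counts `k_social`, `n_social`, `k_community`,
#'   `n_community`.
#' @export
tally_flags <- function(profile, registry = default_indicators(),
                        missing_policy = c("exclude", "error")) {
  missing_policy <- match.arg(missing_policy)
  validate_indicator_registry(registry)
  meas <- profile$measurements
  unknown <- setdiff(meas$indicator_id, registry$id)
  if (length(unknown)) {
    abort(sprintf("profile measures unknown indicator(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "castr_unknown_indicator_error")
  }
  counts <- list(k_social = 0L, n_social = 0L,
                 k_community = 0L, n_community = 0L)
  dropped <- character()
  for (i in seq_len(nrow(registry))) {
    defn <- registry[i, ]
    j <- match(defn$id, meas$indicator_id)
    value <- if (is.na(j)) NA else meas$value[[j]]
    if (length(value) != 1L || is.na(value)) {
      if (missing_policy == "error") {
        abort(sprintf("no measurement for indicator '%s'.", defn$id),
              class = "castr_missing_data_error")
      }
      dropped <- c(dropped, defn$id)
      next
    }
    flag <- evaluate_indicator(defn, value)
    kf <- paste0("k_", defn$group)
    nf <- paste0("n_", defn$group)
    counts[[nf]] <- counts[[nf]] + 1L
    counts[[kf]] <- counts[[kf]] + as.integer(flag)
  }
  if (length(dropped)) {
    warn(sprintf("excluded %d unmeasured indicator(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  counts
}

#' Prevalence ratio of flagged indicators
#'
#' The fraction of a group's evaluable indicators whose measured values
#' exceed (or, for reversed indicators, fall under) their thresholds.
#' An empty group yields 0 with a warning.
#'
#' @param k number of flagged indicators.
#' @param n number of evaluable indicators.
#' @return a proportion in `[0, 1]`.
#' @export
#' @examples
#' prevalence_ratio(7, 11)
prevalence_ratio <- function(k, n) {
  check_count(n, "n")
  check_count(k, "k")
  if (k > n) {
    abort("`k` (flagged) cannot exceed `n` (evaluable).",
          class = "castr_inconsistency_error")
  }
  if (n == 0L) {
    warn("no evaluable indicators in group; prevalence ratio set to 0.")
    return(0)
  }
  k / n
}

#' Social/community risk multiplier
#'
#' Combines the two group-level prevalence ratios into the scalar applied to
#' every component's maximum need. Two readings of the published method are
#' supported:
#'
#' * `mode = "score"` (default): multiplier = ratio_social + ratio_community,
#'   in `[0, 2]`. This reproduces the worked example's printed risk scores
#'   (0.78 and 1.06), which scale the two communities' printed unit counts.
#' * `mode = "equation"`: multiplier = 1 + ratio_social + ratio_community,
#'   in `[1, 3]`, the literal `(1 + R)` reading of the need equation.
#'
#' The displayed `score` is the multiplier rounded to 2 decimals; full
#' precision is retained in `multiplier`.
#'
#' @param ratio_social,ratio_community group prevalence ratios in `[0, 1]`.
#' @param mode `"score"` or `"equation"`.
#' @param counts optional list of flag counts (as from [tally_flags()]) to
#'   carry in the result.
#' @return a `cast_risk` object: counts, ratios, `multiplier`, displayed
#'   `score`, and `mode`.
#' @export
#' @examples
#' risk_multiplier(7 / 11, 1 / 7)$score   # 0.78
#' risk_multiplier(7 / 11, 3 / 7)$score   # 1.06
risk_multiplier <- function(ratio_social, ratio_community,
                            mode = c("score", "equation"), counts = NULL) {
  mode <- match.arg(mode)
  check_proportion(ratio_social, "ratio_social")
  check_proportion(ratio_community, "ratio_community")
  r <- ratio_social + ratio_community
  multiplier <- if (mode == "equation") 1 + r else r
  out <- list(
    n_social = counts$n_social %||% NA_integer_,
    k_social = counts$k_social %||% NA_integer_,
    n_community = counts$n_community %||% NA_integer_,
    k_community = counts$k_community %||% NA_integer_,
    ratio_social = ratio_social,
    ratio_community = ratio_community,
    multiplier = multiplier,
    score = round(multiplier, 2),
    mode = mode
  )
  structure(out, class = "cast_risk")
}

#' @export
print.cast_risk <- function(x, ...) {
  cat(sprintf("<cast_risk> mode = %s\n", x$mode))
  if (!is.na(x$n_social)) {
    cat(sprintf("  social:    %d/%d flagged (ratio %.4f)\n",
                x$k_social, x$n_social, x$ratio_social))
    cat(sprintf("  community: %d/%d flagged (ratio %.4f)\n",
                x$k_community, x$n_community, x$ratio_community))
  }
  cat(sprintf("  multiplier %.6f (displayed risk score %.2f)\n",
              x$multiplier, x$score))
  invisible(x)
}

#' Score a community profile against the indicator registry
#'
#' Convenience wrapper: [tally_flags()] then [prevalence_ratio()] per group
#' then [risk_multiplier()].
#'
#' @inheritParams tally_flags
#' @inheritParams risk_multiplier
#' @return a `cast_risk` object.
#' @export
assess_risk <- function(profile, registry = default_indicators(),
                        mode = c("score", "equation"),
                        missing_policy = c("exclude", "error")) {
  mode <- match.arg(mode)
  counts <- tally_flags(profile, registry, missing_policy)
  risk_multiplier(
    prevalence_ratio(counts$k_social, counts$n_social),
    prevalence_ratio(counts$k_community, counts$n_community),
    mode = mode, counts = counts
  )
}
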