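#' Build a community profile
#'
#' The assessed community's demographics, expected substance-use prevalence,
#' and indicator measurements. `substance_use_prevalence` is the proportion
#' of the population aged 12-65 expected to use substances; communities
#' without precise local data would supply a subregional survey estimate
#' here. Age-band proportions are profile fields (not risk indicators) and
#' enter the computation only through target-population resolution.
#'
#' @param name community label.
#' @param total_population persons, `>= 0`.
#' @param pct_age_10_19,pct_age_20_65,pct_age_12_65 proportions of the total
#'   population in each age band, in `[0, 1]`. Any may be `NA` if no
#'   component selector needs it.
#' @param pct_male proportion male, in `[0, 1]` (descriptive; may be `NA`).
#' @param substance_use_prevalence proportion of the 12-65 population
#'   expected to use substances, in `[0, 1]`.
#' @param measurements a data frame with columns `indicator_id` and `value`
#'   (numeric, or logical for boolean indicators; `NA` = missing), at most
#'   one row per indicator.
#' @return a `community_profile` object.
#' @export
#' @examples
#' community_profile("demo", 50000, pct_age_12_65 = 0.7,
#'                   substance_use_prevalence = 0.1)
community_profile <- function(name, total_population,
                              pct_age_10_19 = NA_real_,
                              pct_age_20_65 = NA_real_,
                              pct_age_12_65 = NA_real_,
                              pct_male = NA_real_,
                              substance_use_prevalence = NA_real_,
                              measurements = NULL) {
  check_nonneg(total_population, "total_population")
  for (f in c("pct_age_10_19", "pct_age_20_65", "pct_age_12_65", "pct_male",
              "substance_use_prevalence")) {
    check_proportion(get(f), f, allow_na = TRUE)
  }
  if (is.null(measurements)) {
    measurements <- tibble::tibble(indicator_id = character(), value = list())
  }
  if (!all(c("indicator_id", "value") %in% names(measurements))) {
    stop_validation("`measurements` needs columns indicator_id and value.")
  }
  if (anyDuplicated(measurements$indicator_id)) {
    stop_validation("duplicate indicator_id among measurements.")
  }
  measurements <- tibble::tibble(
    indicator_id = as.character(measurements$indicator_id),
    value = as.list(measurements$value)
  )
  bad <- vapply(measurements$value, function(v) {
    !is.na(v) && is.numeric(v) && v < 0
  }, logical(1))
  if (any(bad)) {
    stop_domain(sprintf("negative measurement for indicator(s): %s",
                        paste(measurements$indicator_id[bad], collapse = ", ")))
  }
  structure(
    list(name = as.character(name),
         total_population = as.numeric(total_population),
         pct_age_10_19 = pct_age_10_19,
         pct_age_20_65 = pct_age_20_65,
         pct_age_12_65 = pct_age_12_65,
         pct_male = pct_male,
         substance_use_prevalence = substance_use_prevalence,
         measurements = measurements),
    class = "community_profile"
  )
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> %s\n", x$name))
  cat(sprintf("  population %s; prevalence %s; %d indicator measurement(s)\n",
              format(x$total_population, big.mark = ","),
              ifelse(is.na(x$substance_use_prevalence), "unset",
                     format(x$substance_use_prevalence)),
              nrow(x$measurements)))
  invisible(x)
}

profile_fields <- c("name", "total_population", "pct_age_10_19",
                    "pct_age_20_65", "pct_age_12_65", "pct_male",
                    "substance_use_prevalence")

#' Read a community profile from JSON or CSV
#'
#' JSON profiles are an object with the scalar fields of
#' [community_profile()] plus a `measurements` array of
#' `{indicator_id, value}` objects. CSV profiles are long-format
#' `field,value` pairs where indicator measurements use
#' `indicator.<id>` as the field name (boolean values as `true`/`false`).
#' Unknown fields warn but do not fail.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return a validated `community_profile`.
#' @export
read_profile <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop_validation(sprintf("profile file not found: %s", path))
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    meas <- raw$measurements
    if (!is.null(meas) && length(meas)) {
      meas <- tibble::tibble(indicator_id = meas$indicator_id,
                             value = as.list(meas$value))
    } else {
      meas <- NULL
    }
    scalars <- raw[setdiff(names(raw), "measurements")]
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
    if (!all(c("field", "value") %in% names(tab))) {
      stop_validation("CSV profile needs header columns `field,value`.")
    }
    is_meas <- grepl("^indicator\\.", tab$field)
    parse_value <- function(v) {
      if (tolower(v) %in% c("true", "false")) as.logical(toupper(v) == "TRUE")
      else if (v == "" || tolower(v) == "na") NA
      else {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) v else num
      }
    }
    meas <- NULL
    if (any(is_meas)) {
      meas <- tibble::tibble(
        indicator_id = sub("^indicator\\.", "", tab$field[is_meas]),
        value = lapply(tab$value[is_meas], parse_value)
      )
    }
    scalars <- lapply(tab$value[!is_meas], parse_value)
    names(scalars) <- tab$field[!is_meas]
  }
  unknown <- setdiff(names(scalars), profile_fields)
  if (length(unknown)) {
    warn(sprintf("ignoring unknown profile field(s): %s",
                 paste(unknown, collapse = ", ")))
    scalars <- scalars[setdiff(names(scalars), unknown)]
  }
  if (is.null(scalars$total_population)) {
    stop_validation("profile lacks required field `total_population`.")
  }
  args <- c(list(name = scalars$name %||% basename(path)),
            scalars[setdiff(names(scalars), "name")],
            list(measurements = meas))
  do.call(community_profile, args)
}

#' Write a community profile as JSON
#'
#' Inverse of [read_profile()] for the JSON format.
#'
#' @param profile a `community_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  scalars <- unclass(profile)[profile_fields]
  scalars <- scalars[!vapply(scalars, function(v) all(is.na(v)), logical(1))]
  obj <- c(scalars, list(measurements = data.frame(
    indicator_id = profile$measurements$indicator_id,
    value = I(profile$measurements$value)
  )))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
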