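#' Write a need/gap report to disk
#'
#' Three formats: `csv` (one row per component), `json` (rows nested by
#' category plus a provenance block), and `markdown` (a human-readable
#' table: component, recommended units, observed units and gap when
#' present, unit label — with per-category headings).
#'
#' JSON reports round-trip: [read_report()] restores a report equal to the
#' in-memory one. Provenance carries the mode, rounding rule, multiplier,
#' and registry checksums; a timestamp is included only when
#' `timestamp = TRUE` so that identical runs yield byte-identical files.
#'
#' @param report a `cast_report` from [assess_community()] or
#'   [gap_analysis()].
#' @param path output file path.
#' @param format `"csv"`, `"json"`, or `"markdown"`; guessed from the
#'   extension by default (`.csv`, `.json`, `.md`).
#' @param timestamp include a generation timestamp in the provenance block
#'   (default `FALSE`, keeping output deterministic).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("auto", "csv", "json", "markdown"),
                         timestamp = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json", md = "markdown",
                     stop_validation(sprintf(
                       "cannot guess report format from path '%s'.", path)))
  }
  prov <- attr(report, "provenance")
  if (timestamp) prov$generated <- format(Sys.time(), tz = "UTC")
  switch(format,
    csv = write.csv(as.data.frame(report), path, row.names = FALSE),
    json = {
      cats <- unique(report$category)
      by_cat <- lapply(cats, function(cc) {
        rows <- as.data.frame(report[report$category == cc, ])
        rows$category <- NULL
        rows
      })
      names(by_cat) <- cats
      obj <- list(provenance = prov, categories = by_cat,
                  summary = as.data.frame(category_summary(report)))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    },
    markdown = writeLines(report_markdown(report, prov), path)
  )
  invisible(path)
}

report_markdown <- function(report, prov) {
  has_gap <- "gap" %in% names(report)
  header <- if (has_gap) {
    c("| Component | Recommended | Observed | Gap | Type of unit |",
      "|---|---:|---:|---:|---|")
  } else {
    c("| Component | Recommended | Type of unit |",
      "|---|---:|---|")
  }
  lines <- c(
    sprintf("# Community need report: %s", prov$community),
    "",
    sprintf("Risk score %.2f (mode %s, rounding %s, multiplier %.6f)",
            prov$risk_score, prov$mode, prov$rounding, prov$multiplier),
    ""
  )
  for (cc in unique(report$category)) {
    rows <- report[report$category == cc, ]
    lines <- c(lines, sprintf("## %s", cc), "", header)
    for (i in seq_len(nrow(rows))) {
      lines <- c(lines, if (has_gap) {
        sprintf("| %s | %d | %d | %+d | %s |", rows$name[i],
                rows$recommended_units[i], rows$observed_units[i],
                rows$gap[i], rows$unit_label[i])
      } else {
        sprintf("| %s | %d | %s |", rows$name[i],
                rows$recommended_units[i], rows$unit_label[i])
      })
    }
    lines <- c(lines, "")
  }
  lines
}

#' Read a JSON report back into a `cast_report`
#'
#' @param path a JSON file written by [write_report()].
#' @return a `cast_report` tibble with the provenance attribute restored.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rows <- do.call(rbind, lapply(names(obj$categories), function(cc) {
    d <- obj$categories[[cc]]
    d$category <- cc
    d
  }))
  front <- c("component_id", "category", "name", "unit_label")
  rows <- rows[c(front, setdiff(names(rows), front))]
  rows <- tibble::as_tibble(rows)
  int_cols <- intersect(c("recommended_units", "observed_units", "gap"),
                        names(rows))
  for (cn in int_cols) rows[[cn]] <- as.integer(rows[[cn]])
  structure(rows, class = c("cast_report", class(rows)),
            provenance = obj$provenance)
}
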