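#' Round half away from zero
#'
#' Deterministic commercial rounding used to turn real-valued adjusted need
#' into integer unit counts: values exactly halfway between integers round
#' up (2.5 -> 3), unlike [base::round()]'s banker's rounding. Negative
#' inputs never arise in need computation but round symmetrically.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.49, 0.5, 1.5, 2.5))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Apply the configured rounding rule to a real-valued need.
apply_rounding <- function(x, rounding = c("half_up", "ceiling")) {
  rounding <- match.arg(rounding)
  switch(rounding, half_up = round_half_up(x), ceiling = ceiling(x))
}

# Shared argument checks -----------------------------------------------------

stop_domain <- function(msg) abort(msg, class = "castr_domain_error")
stop_validation <- function(msg) abort(msg, class = "castr_validation_error")

check_proportion <- function(x, name, allow_na = FALSE) {
  if (allow_na && (is.null(x) || all(is.na(x)))) return(invisible(x))
  if (is.null(x) || !is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_domain(sprintf("`%s` must be a proportion in [0, 1].", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (is.null(x) || !is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop_domain(sprintf("`%s` must be a non-negative number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < min || x != trunc(x)) {
    stop_domain(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(x)
}
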