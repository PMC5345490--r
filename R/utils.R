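#' Round half away from zero
#'
#' Presentation rounding used throughout the reporting layer: ties go up
#' (2.5 -> 3), unlike [base::round()]'s round-half-even. All cascade
#' arithmetic is done at full precision; this is applied once, at the end.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (>= 0).
#' @return `x` rounded to `digits` decimals, half-up.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13
#' round_half_up(70.45, 1) # 70.5
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# ---- calendar months ("YYYY-MM" strings) -------------------------------

ym_ok <- function(x) {
  grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", x)
}

assert_ym <- function(x, what = "month") {
  bad <- !ym_ok(x)
  if (any(bad)) {
    abort_schema(sprintf(
      "%s values must be 'YYYY-MM'; offending: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

#' @noRd
ym_index <- function(x) {
  # months since year 0, so differences are calendar month steps
  y <- as.integer(substr(x, 1, 4))
  m <- as.integer(substr(x, 6, 7))
  y * 12L + (m - 1L)
}

ym_from_index <- function(i) {
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' Sequence of consecutive calendar months
#'
#' @param from,to months as `"YYYY-MM"` strings.
#' @return character vector of consecutive months, inclusive.
#' @export
#' @examples
#' month_seq("2013-11", "2014-02")
month_seq <- function(from, to) {
  assert_ym(c(from, to))
  ym_from_index(seq(ym_index(from), ym_index(to)))
}

ym_label <- function(x) {
  format(as.Date(paste0(x, "-01")), "%b %Y")
}

# ---- condition helpers -------------------------------------------------

abort_schema <- function(msg) {
  rlang::abort(msg, class = "urchingo_schema_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "urchingo_validation_error")
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = "urchingo_domain_error")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "urchingo_config_error")
}
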