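#' Gonadosomatic index
#'
#' GSI = 100 x gonad wet weight / total wet weight, the fraction of body
#' mass invested in gonads, in percent. Scale-invariant in the two weights.
#'
#' @param gonad_wet gonad wet weight (g), >= 0.
#' @param total_wet total wet weight (g), > 0.
#' @return GSI in percent, in `[0, 100]`; vectorized.
#' @export
#' @examples
#' compute_gsi(2.5, 50) # 5
compute_gsi <- function(gonad_wet, total_wet) {
  if (any(is.na(total_wet)) || any(total_wet <= 0)) {
    abort_domain("total_wet must be > 0")
  }
  if (any(is.na(gonad_wet)) || any(gonad_wet < 0)) {
    abort_domain("gonad_wet must be >= 0")
  }
  if (any(gonad_wet > total_wet)) {
    abort_domain("gonad_wet exceeds total_wet")
  }
  100 * gonad_wet / total_wet
}

#' Assign test diameters to named size classes
#'
#' Classes are half-open `[lower, upper)`; the commercial class is unbounded
#' above, so a TD exactly at the landing size belongs to it. Diameters
#' outside every named class map to `NA`.
#'
#' @param td test diameter(s), mm, > 0.
#' @param scheme a [size_class_scheme()].
#' @return character vector of class names (or `NA`).
#' @export
#' @examples
#' assign_size_class(c(29.9, 45, 50))
assign_size_class <- function(td, scheme = size_class_scheme()) {
  if (any(is.na(td)) || any(td <= 0)) abort_domain("td must be > 0")
  cl <- scheme$classes
  out <- rep(NA_character_, length(td))
  for (i in seq_len(nrow(cl))) {
    out[td >= cl$lower[i] & td < cl$upper[i]] <- cl$name[i]
  }
  out
}

#' Attach GSI and size class to a record table
#'
#' @param records a tibble of urchin records ([read_urchin_records()]).
#' @param config a [pipeline_config()].
#' @return `records` with `gsi` and `size_class` columns added.
#' @export
add_gsi <- function(records, config = pipeline_config()) {
  records$gsi <- compute_gsi(records$gw_g, records$tw_g)
  records$size_class <- assign_size_class(records$td_mm, config$scheme)
  records
}

#' Monthly mean GSI series per (zone, size class) stratum
#'
#' Sexes are pooled by default into a single monthly mean; SE is the sample
#' standard deviation over individuals divided by sqrt(n), with the SE of a
#' singleton month set to 0 by convention (n is carried so callers can
#' filter). Months are calendar strata; months with no data inside a
#' stratum's sampled span are listed by [gap_months()].
#'
#' @param records urchin records; `gsi`/`size_class` columns are added if
#'   absent.
#' @param config a [pipeline_config()].
#' @param zone,size_class optional filters; by default all strata with at
#'   least one classified record are returned.
#' @param sex optional sex filter (used when `config$pool_sexes` is `FALSE`).
#' @return a tibble `zone, size_class, month, mean_gsi, se_gsi, n`, ordered
#'   by stratum and month.
#' @export
gsi_monthly_series <- function(records, config = pipeline_config(),
                               zone = NULL, size_class = NULL, sex = NULL) {
  if (!"gsi" %in% names(records)) records <- add_gsi(records, config)
  df <- records[!is.na(records$size_class), , drop = FALSE]
  if (!is.null(zone)) df <- df[df$zone %in% zone, , drop = FALSE]
  if (!is.null(size_class)) df <- df[df$size_class %in% size_class, , drop = FALSE]
  if (!config$pool_sexes && !is.null(sex)) df <- df[df$sex %in% sex, , drop = FALSE]
  if (nrow(df) == 0) {
    abort_domain("no records for the requested stratum")
  }
  out <- df |>
    dplyr::group_by(.data$zone, .data$size_class, .data$month) |>
    dplyr::summarise(
      mean_gsi = mean(.data$gsi),
      se_gsi = if (dplyr::n() > 1) {
        stats::sd(.data$gsi) / sqrt(dplyr::n())
      } else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$zone, .data$size_class, .data$month)
  out
}

#' Months with no data inside each stratum's sampled span
#'
#' @param series a tibble from [gsi_monthly_series()].
#' @return a tibble `zone, size_class, month` listing the gap months (zero
#'   rows when every stratum is complete).
#' @export
gap_months <- function(series) {
  series |>
    dplyr::group_by(.data$zone, .data$size_class) |>
    dplyr::reframe(
      month = setdiff(
        month_seq(min(.data$month), max(.data$month)),
        .data$month
      )
    )
}
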