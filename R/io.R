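# CSV schemas (comma separator, dot decimal, UTF-8, one header line):
#   urchins.csv   record_id,zone,area,month,td_mm,tw_g,gw_g,sex
#   quadrats.csv  zone,area,quadrat_id[,replicate][,area_m2],<bin columns>
#   fertility.csv zone,month[,size_class],eggs_total,eggs_fertilized,
#                 plutei_scored,plutei_total

read_csv_strict <- function(path, what, character_cols = character(0)) {
  if (!file.exists(path)) {
    abort_schema(sprintf("%s file not found: %s", what, path))
  }
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  character_cols <- intersect(character_cols, hdr)
  spec <- do.call(
    readr::cols,
    stats::setNames(rep(list(readr::col_character()), length(character_cols)),
                    character_cols)
  )
  readr::read_csv(path, col_types = spec, show_col_types = FALSE,
                  progress = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_schema(sprintf(
      "%s: missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
}

#' Read individual sea urchin records
#'
#' One row per measured individual: test diameter (mm, without spines),
#' total wet weight (g), gonad wet weight (g), with zone/area/month/sex
#' metadata. Every row is validated; nothing is silently dropped.
#'
#' @param path path to a `urchins.csv`-schema file.
#' @param config a [pipeline_config()].
#' @param strict if `TRUE` (default) any invalid row aborts with a message
#'   naming the offending `record_id`s; if `FALSE`, invalid rows are removed
#'   with a warning and returned in the `"rejected"` attribute.
#' @return a tibble of validated records (columns `record_id`, `zone`,
#'   `area`, `month`, `td_mm`, `tw_g`, `gw_g`, `sex`).
#' @export
read_urchin_records <- function(path, config = pipeline_config(),
                                strict = TRUE) {
  df <- read_csv_strict(path, "urchin records",
                        character_cols = c("record_id", "zone", "area",
                                           "month", "sex"))
  cols <- c("record_id", "zone", "area", "month", "td_mm", "tw_g", "gw_g", "sex")
  require_columns(df, cols, "urchin records")
  df <- tibble::as_tibble(df)[cols]
  if (nrow(df) == 0) {
    rlang::warn(sprintf("urchin records: %s has a header but no rows", path))
    return(df)
  }
  df$record_id <- as.character(df$record_id)
  df$month <- as.character(df$month)
  assert_ym(df$month, "urchin records: month")
  df$sex <- ifelse(is.na(df$sex), "unknown", as.character(df$sex))
  bad_sex <- !df$sex %in% c("F", "M", "unknown")
  if (any(bad_sex)) {
    abort_validation(sprintf(
      "sex must be F, M or unknown; offending record(s): %s",
      paste(df$record_id[bad_sex], collapse = ", ")
    ))
  }
  problems <- validate_urchins(df, config)
  if (length(problems$bad)) {
    msg <- sprintf(
      "%d invalid urchin record(s): %s",
      length(problems$bad), paste(problems$msgs, collapse = "; ")
    )
    if (strict) abort_validation(msg)
    rlang::warn(msg)
    rejected <- df[problems$bad, , drop = FALSE]
    df <- df[-problems$bad, , drop = FALSE]
    attr(df, "rejected") <- rejected
  }
  df
}

validate_urchins <- function(df, config) {
  tdb <- config$scheme$td_bounds
  checks <- list(
    list(is.na(df$td_mm) | df$td_mm <= tdb[1] | df$td_mm >= tdb[2],
         sprintf("td_mm outside (%g, %g)", tdb[1], tdb[2])),
    list(is.na(df$tw_g) | df$tw_g <= 0, "tw_g must be > 0"),
    list(is.na(df$gw_g) | df$gw_g < 0, "gw_g must be >= 0"),
    list(!is.na(df$gw_g) & !is.na(df$tw_g) & df$gw_g > df$tw_g,
         "gonad weight exceeds total weight")
  )
  bad <- integer(0)
  msgs <- character(0)
  for (ch in checks) {
    idx <- which(ch[[1]])
    if (length(idx)) {
      bad <- union(bad, idx)
      msgs <- c(msgs, sprintf(
        "%s (%s)", ch[[2]], paste(df$record_id[idx], collapse = ", ")
      ))
    }
  }
  list(bad = sort(bad), msgs = msgs)
}

#' Read quadrat census counts
#'
#' One row per quadrat; one column per 10-mm census bin (labels like
#' `"40-50"`, `"60+"`; see [parse_bin_labels()] for accepted spellings).
#' An `area_m2` column is optional (the configured quadrat area is attached
#' when absent), as is a `replicate` column naming the survey's replicate
#' block within each area.
#'
#' @param path path to a `quadrats.csv`-schema file.
#' @param config a [pipeline_config()].
#' @return a tibble with columns `zone`, `area`, `quadrat_id`, `replicate`,
#'   `area_m2` and one count column per census bin (canonical labels).
#' @export
read_quadrat_counts <- function(path, config = pipeline_config()) {
  df <- read_csv_strict(path, "quadrat counts",
                        character_cols = c("zone", "area", "quadrat_id",
                                           "replicate"))
  require_columns(df, c("zone", "area", "quadrat_id"), "quadrat counts")
  df <- tibble::as_tibble(df)
  if (!"replicate" %in% names(df)) df$replicate <- "R1"
  if (!"area_m2" %in% names(df)) df$area_m2 <- config$quadrat_area
  if (any(is.na(df$area_m2) | df$area_m2 <= 0)) {
    abort_validation("quadrat area_m2 must be > 0 for every quadrat")
  }
  meta <- c("zone", "area", "quadrat_id", "replicate", "area_m2")
  bin_cols <- setdiff(names(df), meta)
  if (!length(bin_cols)) abort_schema("quadrat counts: no size-bin columns found")
  canonical <- match_bins_to_scheme(bin_cols, config$scheme)
  counts <- df[bin_cols]
  for (j in seq_along(bin_cols)) {
    x <- counts[[j]]
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      abort_validation(sprintf(
        "counts in bin '%s' must be nonnegative integers; offending quadrat(s): %s",
        bin_cols[j], paste(df$quadrat_id[bad], collapse = ", ")
      ))
    }
  }
  names(counts) <- canonical
  out <- dplyr::bind_cols(df[meta], counts[census_bin_labels(config$scheme)[
    census_bin_labels(config$scheme) %in% canonical
  ]])
  # bins absent from the file are zero-filled so all quadrats share the scheme
  for (lab in setdiff(census_bin_labels(config$scheme), canonical)) {
    out[[lab]] <- 0
  }
  out[c(meta, census_bin_labels(config$scheme))]
}

#' Read fertility assay counts
#'
#' One row per assay: eggs scored, eggs fertilized, and optionally counts of
#' larvae reaching the four-arm pluteus stage (`plutei_total` may be `NA`
#' when no larval count was done). Assays without a `size_class` column are
#' attributed to the undersized fertile class `"US"`, the class the assays
#' target in the field protocol.
#'
#' @param path path to a `fertility.csv`-schema file.
#' @return a validated tibble.
#' @export
read_fertility_assays <- function(path) {
  df <- read_csv_strict(path, "fertility assays",
                        character_cols = c("zone", "month", "size_class"))
  require_columns(df, c("zone", "month", "eggs_total", "eggs_fertilized"),
                  "fertility assays")
  df <- tibble::as_tibble(df)
  if (!"size_class" %in% names(df)) df$size_class <- "US"
  if (!"plutei_scored" %in% names(df)) df$plutei_scored <- NA_real_
  if (!"plutei_total" %in% names(df)) df$plutei_total <- NA_real_
  df$month <- as.character(df$month)
  assert_ym(df$month, "fertility assays: month")
  if (any(is.na(df$eggs_total) | df$eggs_total <= 0)) {
    abort_validation("eggs_total must be > 0 for every assay")
  }
  bad <- is.na(df$eggs_fertilized) | df$eggs_fertilized < 0 |
    df$eggs_fertilized > df$eggs_total
  if (any(bad)) {
    abort_validation(sprintf(
      "eggs_fertilized must be in [0, eggs_total]; offending row(s): %s",
      paste(which(bad), collapse = ", ")
    ))
  }
  bad_pl <- !is.na(df$plutei_total) &
    (is.na(df$plutei_scored) | df$plutei_scored > df$plutei_total)
  if (any(bad_pl)) {
    abort_validation(sprintf(
      "plutei_scored must be <= plutei_total; offending row(s): %s",
      paste(which(bad_pl), collapse = ", ")
    ))
  }
  df[c("zone", "month", "size_class", "eggs_total", "eggs_fertilized",
       "plutei_scored", "plutei_total")]
}

#' Write pipeline tables as CSV
#'
#' Plain comma/dot/UTF-8 CSV with one header line; the inverse of the
#' corresponding readers, so write-then-read round-trips all fields.
#'
#' @param x a tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
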