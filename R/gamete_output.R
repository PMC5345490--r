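#' Gamete output per square metre
#'
#' GO = IGO x natural density of the class (g g^-1 m^-2 per spawning
#' event): the gonad-mass fraction released by one average individual,
#' scaled by how many such individuals occupy a square metre.
#'
#' @param igo individual gamete output (g g^-1 per event), >= 0.
#' @param density natural density of the size class (ind m^-2), >= 0.
#' @return GO at full precision; vectorized.
#' @export
#' @examples
#' gamete_output_per_m2(0.031, 2.7) # 0.0837
gamete_output_per_m2 <- function(igo, density) {
  if (any(is.na(igo)) || any(igo < 0)) abort_domain("igo must be >= 0")
  if (any(is.na(density)) || any(density < 0)) {
    abort_domain("density must be >= 0")
  }
  igo * density
}

#' Annual totals of a size class
#'
#' TGO and MGO are the sum and the mean of the class's per-event GO over
#' the year (g g^-1 m^-2 yr^-1); with a single event they coincide.
#'
#' @param gos per-event GO values of one class (non-empty).
#' @return a list with `tgo` and `mgo`.
#' @export
#' @examples
#' class_totals(c(0.1134, 0.0783))
class_totals <- function(gos) {
  if (length(gos) == 0) {
    abort_domain("class produced no events: totals undefined")
  }
  if (any(is.na(gos)) || any(gos < 0)) abort_domain("GO values must be >= 0")
  list(tgo = sum(gos), mgo = sum(gos) / length(gos))
}

#' Population totals across fertile classes
#'
#' popTGO and popMGO are the sums of the class TGOs and of the class MGOs —
#' the population's annual and mean-per-event reproductive contribution per
#' square metre. (popMGO is a sum, not a mean, of class MGOs: each class
#' contributes its own average event output.)
#'
#' @param class_df a data frame with columns `tgo` and `mgo`, one row per
#'   fertile class.
#' @return a list with `pop_tgo` and `pop_mgo`.
#' @export
population_totals <- function(class_df) {
  if (nrow(class_df) == 0) abort_domain("no fertile classes present")
  list(pop_tgo = sum(class_df$tgo), pop_mgo = sum(class_df$mgo))
}

#' Summarize fertility assays
#'
#' Fertilization percentage per assay, success flag against the threshold
#' (inclusive: "at least"), and pluteus percentage where larval counts were
#' done.
#'
#' @param assays a tibble from [read_fertility_assays()] or
#'   [simulate_fertility()].
#' @param threshold minimum fertilization percentage for success
#'   (default 80).
#' @return the assay tibble with `fertilization_pct`, `success` and
#'   `pluteus_pct` columns appended.
#' @export
fertility_summary <- function(assays, threshold = 80) {
  if (any(assays$eggs_total <= 0)) abort_domain("eggs_total must be > 0")
  assays$fertilization_pct <- 100 * assays$eggs_fertilized / assays$eggs_total
  assays$success <- assays$fertilization_pct >= threshold
  assays$pluteus_pct <- ifelse(
    is.na(assays$plutei_total) | assays$plutei_total == 0,
    NA_real_,
    100 * assays$plutei_scored / assays$plutei_total
  )
  assays
}

round_metric <- function(value, metric, config) {
  pct <- metric %in% c("pre_gsi", "post_gsi", "magnitude")
  digits <- ifelse(pct, config$pct_digits, config$gg_digits)
  # densities share the 1-decimal convention of the census tables
  digits[metric == "density"] <- config$pct_digits
  round_half_up(value, digits)
}

#' Build the gamete-output report
#'
#' Combines detected spawning events, fertile-class densities and (when
#' available) fertility assays into the per-class, per-event gamete-output
#' cascade and the population totals. All arithmetic is carried at full
#' precision; the rounded presentation values are computed from the
#' full-precision intermediates in a single final rounding step (rounded
#' values are never fed back into the cascade).
#'
#' Classes flagged non-fertile in the scheme never enter the report. A class
#' with assay data is kept only when the majority of its assays meet the
#' fertilization threshold; classes without assays are taken as fertile on
#' the strength of the scheme flag alone.
#'
#' @param events a tibble from [detect_events()] (or assembled directly;
#'   needs `zone, size_class, event, start_month, end_month, pre_gsi,
#'   post_gsi`; `igo`/`magnitude` are recomputed if absent).
#' @param densities a tibble with `zone, size_class, density` — e.g. from
#'   [fertile_class_density()].
#' @param fertility optional assay tibble ([read_fertility_assays()]).
#' @param config a [pipeline_config()].
#' @return an object of class `gamete_output_table`: a list with
#'   * `classes`: per (zone, class, event) rows with `go`, plus class `tgo`
#'     and `mgo` (full precision);
#'   * `population`: per-zone `pop_tgo`, `pop_mgo`;
#'   * `table`: the long-format report (`zone, size_class, event, metric,
#'     value_full, value_rounded`);
#'   * `text`: an aligned text rendering of the summary table.
#' @export
build_report <- function(events, densities, fertility = NULL,
                         config = pipeline_config()) {
  cl <- config$scheme$classes
  fertile_names <- cl$name[cl$fertile]
  ev <- events[events$size_class %in% fertile_names, , drop = FALSE]
  if (nrow(ev) == 0) abort_domain("no events in fertile size classes")

  if (!is.null(fertility) && nrow(fertility) > 0) {
    fs <- fertility_summary(fertility, config$fertility_threshold)
    gate <- fs |>
      dplyr::group_by(.data$zone, .data$size_class) |>
      dplyr::summarise(pass = mean(.data$success) > 0.5, .groups = "drop")
    failing <- gate[!gate$pass, c("zone", "size_class")]
    if (nrow(failing)) {
      rlang::inform(sprintf(
        "excluding class(es) failing the fertility threshold: %s",
        paste(failing$zone, failing$size_class, sep = "/", collapse = ", ")
      ))
      ev <- dplyr::anti_join(ev, failing, by = c("zone", "size_class"))
      if (nrow(ev) == 0) abort_domain("all classes failed the fertility gate")
    }
  }

  dens <- densities[c("zone", "size_class", "density")]
  missing <- dplyr::anti_join(
    dplyr::distinct(ev[c("zone", "size_class")]), dens,
    by = c("zone", "size_class")
  )
  if (nrow(missing)) {
    abort_config(sprintf(
      "event class(es) with no density row: %s",
      paste(missing$zone, missing$size_class, sep = "/", collapse = ", ")
    ))
  }

  if (!"igo" %in% names(ev)) {
    ev$igo <- individual_gamete_output(ev$pre_gsi, ev$post_gsi)
  }
  if (!"magnitude" %in% names(ev)) {
    ev$magnitude <- spawning_magnitude(ev$pre_gsi, ev$post_gsi)
  }
  classes <- ev |>
    dplyr::inner_join(dens, by = c("zone", "size_class")) |>
    dplyr::mutate(go = gamete_output_per_m2(.data$igo, .data$density)) |>
    dplyr::group_by(.data$zone, .data$size_class) |>
    dplyr::mutate(tgo = sum(.data$go), mgo = sum(.data$go) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$zone, .data$size_class, .data$event)

  population <- classes |>
    dplyr::distinct(.data$zone, .data$size_class, .data$tgo, .data$mgo) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      pop_tgo = sum(.data$tgo), pop_mgo = sum(.data$mgo), .groups = "drop"
    )

  long_ev <- classes |>
    tidyr::pivot_longer(
      cols = c("pre_gsi", "post_gsi", "igo", "magnitude", "density", "go"),
      names_to = "metric", values_to = "value_full"
    ) |>
    dplyr::select("zone", "size_class", "event", "metric", "value_full")
  long_cl <- classes |>
    dplyr::distinct(.data$zone, .data$size_class, .data$tgo, .data$mgo) |>
    tidyr::pivot_longer(c("tgo", "mgo"),
      names_to = "metric", values_to = "value_full"
    ) |>
    dplyr::mutate(event = NA_integer_) |>
    dplyr::select("zone", "size_class", "event", "metric", "value_full")
  long_pop <- population |>
    tidyr::pivot_longer(c("pop_tgo", "pop_mgo"),
      names_to = "metric", values_to = "value_full"
    ) |>
    dplyr::mutate(size_class = NA_character_, event = NA_integer_) |>
    dplyr::select("zone", "size_class", "event", "metric", "value_full")
  table <- dplyr::bind_rows(long_ev, long_cl, long_pop)
  table$value_rounded <- round_metric(table$value_full, table$metric, config)

  out <- structure(
    list(
      classes = classes, population = population, table = table,
      config = config
    ),
    class = "gamete_output_table"
  )
  out$text <- render_report_text(out)
  out
}

fmt_num <- function(x, digits) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

render_report_text <- function(report) {
  cfg <- report$config
  cls <- report$classes
  pop <- report$population
  col_meta <- cls[c("zone", "size_class", "event")]
  header <- sprintf("%s %s e%d", col_meta$zone, col_meta$size_class, col_meta$event)
  rows <- list(
    "Spawning start" = ym_label(cls$start_month),
    "Spawning end" = ym_label(cls$end_month),
    "Pre-spawning GSI (%)" = fmt_num(cls$pre_gsi, cfg$pct_digits),
    "Post-spawning GSI (%)" = fmt_num(cls$post_gsi, cfg$pct_digits),
    "IGO (g/g per event)" = fmt_num(cls$igo, cfg$gg_digits),
    "Spawning magnitude (%)" = fmt_num(cls$magnitude, cfg$pct_digits),
    "Natural density (ind/m2)" = fmt_num(cls$density, cfg$pct_digits),
    "GO (g/g/m2 per event)" = fmt_num(cls$go, cfg$gg_digits),
    "TGO (g/g/m2/yr)" = fmt_num(cls$tgo, cfg$gg_digits),
    "MGO (g/g/m2/yr)" = fmt_num(cls$mgo, cfg$gg_digits)
  )
  w0 <- max(nchar(names(rows)))
  wc <- pmax(nchar(header), 8)
  line <- function(label, vals) {
    paste0(
      formatC(label, width = w0, flag = "-"), "  ",
      paste(mapply(formatC, vals, width = wc), collapse = "  ")
    )
  }
  lines <- c(
    line("", header),
    unlist(lapply(names(rows), function(nm) line(nm, rows[[nm]])))
  )
  pop_lines <- sprintf(
    "%s: popTGO %s, popMGO %s (g/g/m2/yr)",
    pop$zone,
    fmt_num(pop$pop_tgo, cfg$gg_digits),
    fmt_num(pop$pop_mgo, cfg$gg_digits)
  )
  paste(c(lines, "", pop_lines), collapse = "\n")
}

#' @export
print.gamete_output_table <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}
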