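#' Individual gamete output of a spawning event
#'
#' The drop of mean monthly GSI from the pre-spawning peak to the
#' post-spawning trough, re-expressed as gonad wet weight released per unit
#' body wet weight (g g^-1 per spawning event): IGO = (pre - post) / 100.
#' Full precision is retained; presentation rounding (2 decimals, half-up)
#' happens only in reports.
#'
#' @param pre_gsi pre-spawning mean monthly GSI (%), > `post_gsi`.
#' @param post_gsi post-spawning mean monthly GSI (%), >= 0.
#' @return IGO in g g^-1 per spawning event; vectorized.
#' @export
#' @examples
#' individual_gamete_output(4.4, 1.3) # 0.031
individual_gamete_output <- function(pre_gsi, post_gsi) {
  if (any(is.na(post_gsi)) || any(post_gsi < 0)) {
    abort_domain("post_gsi must be >= 0")
  }
  if (any(is.na(pre_gsi)) || any(pre_gsi <= post_gsi)) {
    abort_domain("pre_gsi must exceed post_gsi (no spawning decline otherwise)")
  }
  (pre_gsi - post_gsi) / 100
}

#' Spawning magnitude
#'
#' The fraction of pre-spawning gonad mass released by the event:
#' 100 x (pre - post) / pre, in percent. A complete spawn-out (post = 0)
#' gives 100 regardless of the peak height.
#'
#' @inheritParams individual_gamete_output
#' @return magnitude in percent; vectorized.
#' @export
#' @examples
#' spawning_magnitude(4.4, 1.3) # 70.45...
spawning_magnitude <- function(pre_gsi, post_gsi) {
  if (any(is.na(pre_gsi)) || any(pre_gsi <= 0)) {
    abort_domain("pre_gsi must be > 0")
  }
  if (any(is.na(post_gsi)) || any(post_gsi < 0) || any(post_gsi >= pre_gsi)) {
    abort_domain("post_gsi must be in [0, pre_gsi)")
  }
  100 * (pre_gsi - post_gsi) / pre_gsi
}

# Detection on one stratum. months/means ordered, months as "YYYY-MM".
detect_one_stratum <- function(month, mean_gsi, min_drop, min_rise,
                               min_range_drop, min_span,
                               interpolate_gaps = FALSE) {
  if (interpolate_gaps) {
    idx <- ym_index(month)
    full <- seq(min(idx), max(idx))
    gap <- setdiff(full, idx)
    single <- gap[!(gap - 1) %in% gap & !(gap + 1) %in% gap]
    if (length(single)) {
      filled <- stats::approx(idx, mean_gsi, xout = sort(c(idx, single)))
      month <- ym_from_index(filled$x)
      mean_gsi <- filled$y
    }
  }
  # collapse runs of equal adjacent means; ties resolve to the earliest month
  keep <- c(TRUE, diff(mean_gsi) != 0)
  m <- month[keep]
  v <- mean_gsi[keep]
  k <- length(v)
  if (k < 2) return(NULL) # flat series: no extrema, no events
  is_max <- vapply(seq_len(k), function(i) {
    (i == 1 || v[i] > v[i - 1]) && (i == k || v[i] > v[i + 1])
  }, logical(1))

  # peak qualification: a local max is a spawning peak when it rises at
  # least min_rise % above the running minimum since the previous peak;
  # the first data point (if a local max) always qualifies.
  peaks <- integer(0)
  runmin <- Inf
  for (i in seq_len(k)) {
    qualifies <- is_max[i] && (
      length(peaks) == 0 || # opening peak: no preceding trough to rise from
        (is.finite(runmin) && runmin == 0 && v[i] > 0) ||
        (is.finite(runmin) && runmin > 0 &&
           100 * (v[i] - runmin) / runmin >= min_rise)
    )
    if (qualifies) {
      peaks <- c(peaks, i)
      runmin <- Inf
    } else {
      runmin <- min(runmin, v[i])
    }
  }
  if (!length(peaks)) return(NULL)

  annual_range <- max(v) - min(v)
  events <- list()
  bounds <- c(peaks, k + 1L)
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    seg <- seq(p + 1L, length.out = max(0L, bounds[j + 1L] - p - 1L))
    if (!length(seg)) next
    t_rel <- which.min(v[seg]) # earliest on ties
    t <- seg[t_rel]
    drop_pct <- 100 * (v[p] - v[t]) / v[p]
    span <- ym_index(m[t]) - ym_index(m[p])
    if (v[p] > v[t] && drop_pct >= min_drop &&
        (v[p] - v[t]) >= min_range_drop / 100 * annual_range &&
        span >= min_span) {
      events[[length(events) + 1L]] <- tibble::tibble(
        start_month = m[p], end_month = m[t],
        pre_gsi = v[p], post_gsi = v[t]
      )
    }
  }
  if (!length(events)) return(NULL)
  dplyr::bind_rows(events)
}

#' Detect spawning events in monthly GSI series
#'
#' A spawning event is a sustained decline of the monthly mean GSI from a
#' local peak (the pre-spawning month) to the subsequent trough (the
#' post-spawning month). Within each (zone, size class) stratum:
#'
#' * runs of equal adjacent means are collapsed to their earliest month;
#' * a local maximum qualifies as a spawning peak only if it rises at least
#'   `min_rise` % above the running minimum of the series since the previous
#'   peak (the series' first local maximum always qualifies — it has no
#'   preceding trough to rise from) — this keeps month-to-month noise inside
#'   a long decline from splitting one event in two;
#' * each peak is paired with the lowest subsequent mean before the next
#'   peak (earliest month on ties);
#' * the pair is reported as an event when its relative drop
#'   100 x (pre - post)/pre is at least `min_drop` %, its absolute drop is
#'   at least `min_range_drop` % of the stratum's annual GSI range (pre-
#'   and post-spawning months correspond to the year's highest and lowest
#'   means, so a genuine event spans most of the annual excursion while a
#'   noise wiggle does not), and it spans at least `min_span` calendar
#'   months.
#'
#' Events are therefore disjoint and time-ordered. Missing months are
#' skipped (the series is treated as irregularly spaced) unless
#' `config$interpolate_gaps` fills single-month gaps linearly. Detection
#' uses the mean GSI only; SEs are ignored. A monotone non-decreasing series
#' yields no events (not an error).
#'
#' @param series a tibble from [gsi_monthly_series()] (columns `zone`,
#'   `size_class`, `month`, `mean_gsi`); each stratum needs >= 3 months.
#' @param config a [pipeline_config()]; `min_drop` defaults to 30%,
#'   inferred from the magnitudes typical of true spawning declines
#'   (>= ~50%) versus ordinary monthly fluctuation.
#' @return a tibble `zone, size_class, event, start_month, end_month,
#'   pre_gsi, post_gsi, igo, magnitude` (full precision; zero rows when no
#'   stratum has an event).
#' @export
detect_events <- function(series, config = pipeline_config()) {
  strata <- dplyr::group_split(
    dplyr::group_by(series, .data$zone, .data$size_class)
  )
  out <- lapply(strata, function(s) {
    s <- dplyr::arrange(s, .data$month)
    if (nrow(s) < 3) {
      abort_domain(sprintf(
        "stratum %s/%s has %d month(s); >= 3 needed for event detection",
        s$zone[1], s$size_class[1], nrow(s)
      ))
    }
    ev <- detect_one_stratum(
      s$month, s$mean_gsi,
      min_drop = config$min_drop, min_rise = config$min_rise,
      min_range_drop = config$min_range_drop, min_span = config$min_span,
      interpolate_gaps = config$interpolate_gaps
    )
    if (is.null(ev)) return(NULL)
    ev$zone <- s$zone[1]
    ev$size_class <- s$size_class[1]
    ev$event <- seq_len(nrow(ev))
    ev
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      zone = character(), size_class = character(), event = integer(),
      start_month = character(), end_month = character(),
      pre_gsi = numeric(), post_gsi = numeric(),
      igo = numeric(), magnitude = numeric()
    ))
  }
  out$igo <- individual_gamete_output(out$pre_gsi, out$post_gsi)
  out$magnitude <- spawning_magnitude(out$pre_gsi, out$post_gsi)
  out[c("zone", "size_class", "event", "start_month", "end_month",
        "pre_gsi", "post_gsi", "igo", "magnitude")]
}
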