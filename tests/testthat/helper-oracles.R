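# Independent re-implementations used as oracles. Written as plain loops so
# they share no code path with the package internals they check.

# Brute-force monthly aggregation: mean/SE/n per (zone, size_class, month).
oracle_monthly_stats <- function(records, zone, size_class, month) {
  gsi <- c()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    cls <- NA_character_
    if (r$td_mm >= 30 && r$td_mm < 40) cls <- "Small-US"
    if (r$td_mm >= 40 && r$td_mm < 50) cls <- "US"
    if (r$td_mm >= 50) cls <- "CS"
    if (identical(r$zone, zone) && identical(cls, size_class) &&
        identical(r$month, month)) {
      gsi <- c(gsi, 100 * r$gw_g / r$tw_g)
    }
  }
  n <- length(gsi)
  list(
    mean = sum(gsi) / n,
    se = if (n > 1) sqrt(sum((gsi - sum(gsi) / n)^2) / (n - 1)) / sqrt(n) else 0,
    n = n
  )
}

# Spawning-event detection, recoded from the documented definition:
# collapse tied runs, find alternating local extrema, qualify peaks by the
# rise rule (first local max always qualifies), pair each peak with the
# lowest subsequent mean before the next peak, keep pairs passing the
# relative-drop, range-fraction and span thresholds.
oracle_detect <- function(month, v, min_drop = 30, min_rise = 30,
                          min_range_drop = 30, min_span = 1) {
  keep <- rep(TRUE, length(v))
  for (i in seq_along(v)[-1]) if (v[i] == v[i - 1]) keep[i] <- FALSE
  m <- month[keep]
  x <- v[keep]
  n <- length(x)
  if (n < 2) return(NULL)
  mi <- function(s) { # months since year 0
    as.integer(substr(s, 1, 4)) * 12L + as.integer(substr(s, 6, 7)) - 1L
  }
  locmax <- logical(n)
  for (i in seq_len(n)) {
    locmax[i] <- (i == 1 || x[i] > x[i - 1]) && (i == n || x[i] > x[i + 1])
  }
  peaks <- integer(0)
  for (i in which(locmax)) {
    if (length(peaks) == 0) {
      peaks <- i
    } else {
      between <- (max(peaks) + 1):(i - 1)
      lo <- min(x[between])
      ok <- (lo == 0 && x[i] > 0) ||
        (lo > 0 && 100 * (x[i] - lo) / lo >= min_rise)
      if (ok) peaks <- c(peaks, i)
    }
  }
  if (length(peaks) == 0) return(NULL)
  rng <- max(x) - min(x)
  out <- NULL
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    hi <- if (j < length(peaks)) peaks[j + 1] - 1L else n
    if (hi <= p) next
    seg <- (p + 1):hi
    t <- seg[which.min(x[seg])]
    drop <- x[p] - x[t]
    if (drop > 0 && 100 * drop / x[p] >= min_drop &&
        drop >= min_range_drop / 100 * rng &&
        mi(m[t]) - mi(m[p]) >= min_span) {
      out <- rbind(out, data.frame(
        start_month = m[p], end_month = m[t],
        pre_gsi = x[p], post_gsi = x[t]
      ))
    }
  }
  out
}

# Random monthly GSI series for property tests.
random_series <- function(n_months = 12, start = "2013-06") {
  months <- month_seq(start, "2020-12")[seq_len(n_months)]
  tibble::tibble(
    zone = "Z", size_class = "CS", month = months,
    mean_gsi = round(stats::runif(n_months, 0, 8), 2),
    se_gsi = 0, n = 5L
  )
}

# Minimal well-formed urchin record table.
make_records <- function(td, gw, tw, zone = "HP", month = "2013-06",
                         sex = "F") {
  n <- max(length(td), length(gw), length(tw), length(month))
  tibble::tibble(
    record_id = sprintf("r%02d", seq_len(n)),
    zone = zone, area = paste0(zone, "-A1"),
    month = rep_len(month, n),
    td_mm = rep_len(td, n), tw_g = rep_len(tw, n), gw_g = rep_len(gw, n),
    sex = rep_len(sex, n)
  )
}

expected_zone_summary <- function() {
  # frozen reference cascade for the shipped example summary (rounded as
  # reported: 2 dp for g/g quantities, 1 dp for percentages)
  list(
    igo = c(HP_US = 0.03, HP_CS = 0.05, LP_US_1 = 0.04, LP_US_2 = 0.03,
            LP_CS_1 = 0.04, LP_CS_2 = 0.03),
    magnitude = c(HP_US = 70.5, HP_CS = 75.8, LP_US_1 = 80.8, LP_US_2 = 70.0,
                  LP_CS_1 = 62.7, LP_CS_2 = 53.7),
    go = c(HP_US = 0.08, HP_CS = 0.03, LP_US_1 = 0.02, LP_US_2 = 0.01,
           LP_CS_1 = 0.11, LP_CS_2 = 0.08),
    tgo = c(HP_US = 0.08, HP_CS = 0.03, LP_US = 0.03, LP_CS = 0.19),
    mgo = c(HP_US = 0.08, HP_CS = 0.03, LP_US = 0.01, LP_CS = 0.10),
    pop_tgo = c(HP = 0.11, LP = 0.22),
    pop_mgo = c(HP = 0.11, LP = 0.11)
  )
}

report_cell <- function(report, zone, size_class = NA, event = NA, metric) {
  tb <- report$table
  sel <- tb$metric == metric & tb$zone == zone &
    (is.na(size_class) | (!is.na(tb$size_class) & tb$size_class == size_class)) &
    (is.na(event) | (!is.na(tb$event) & tb$event == event))
  if (!is.na(size_class) && is.na(event)) sel <- sel & is.na(tb$event)
  if (is.na(size_class)) sel <- sel & is.na(tb$size_class)
  vals <- unique(tb$value_rounded[sel])
  stopifnot(length(vals) == 1)
  vals
}
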