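#' Size-class scheme: census bins and named fertility classes
#'
#' Two partitions of test diameter (TD, mm without spines) are used side by
#' side. The census partition is the 10-mm binning of quadrat counts
#' (`0-10`, `10-20`, ..., `60+`), half-open `[lo, hi)` with the last bin
#' unbounded. The fertility partition names the classes whose reproductive
#' role differs: `Small-US` `[30, 40)` (gonads present but effectively
#' infertile), `US` `[40, 50)` (fertile, below the legal landing size) and
#' `CS` `[50, Inf)` (commercial size). The `CS` lower bound equals the legal
#' minimum landing size (50 mm by default).
#'
#' @param census_breaks ascending numeric breakpoints of the census bins;
#'   the last must be `Inf`.
#' @param class_names,class_lower,class_upper,class_fertile parallel vectors
#'   defining the named classes (half-open intervals, `upper` may be `Inf`).
#' @param min_landing_size legal minimum landing size in mm TD; must equal
#'   the lower bound of the commercial class (the last named class).
#' @param td_bounds sanity bounds (mm) for individual test diameters.
#' @return an object of class `size_class_scheme`.
#' @export
#' @examples
#' sch <- size_class_scheme()
#' census_bin_labels(sch)
size_class_scheme <- function(census_breaks = c(0, 10, 20, 30, 40, 50, 60, Inf),
                              class_names = c("Small-US", "US", "CS"),
                              class_lower = c(30, 40, 50),
                              class_upper = c(40, 50, Inf),
                              class_fertile = c(FALSE, TRUE, TRUE),
                              min_landing_size = 50,
                              td_bounds = c(5, 120)) {
  if (length(census_breaks) < 2 || is.unsorted(census_breaks, strictly = TRUE)) {
    abort_config("census_breaks must be strictly ascending")
  }
  if (!is.infinite(census_breaks[length(census_breaks)])) {
    abort_config("the last census break must be Inf (open-topped bin)")
  }
  k <- length(class_names)
  if (length(class_lower) != k || length(class_upper) != k ||
      length(class_fertile) != k) {
    abort_config("class_* vectors must have one entry per named class")
  }
  if (any(class_lower >= class_upper)) {
    abort_config("each named class needs lower < upper")
  }
  if (is.unsorted(class_lower, strictly = TRUE) ||
      any(class_upper[-k] > class_lower[-1])) {
    abort_config("named classes must be ascending and non-overlapping")
  }
  if (class_lower[k] != min_landing_size) {
    abort_config(sprintf(
      "commercial class must start at the minimum landing size (%g mm)",
      min_landing_size
    ))
  }
  if (length(td_bounds) != 2 || td_bounds[1] <= 0 || td_bounds[1] >= td_bounds[2]) {
    abort_config("td_bounds must be c(lower, upper) with 0 < lower < upper")
  }
  structure(
    list(
      census_breaks = census_breaks,
      classes = tibble::tibble(
        name = class_names, lower = class_lower,
        upper = class_upper, fertile = class_fertile
      ),
      min_landing_size = min_landing_size,
      td_bounds = td_bounds
    ),
    class = "size_class_scheme"
  )
}

#' Labels of the census bins
#'
#' Bins are serialized as `"lo-hi"` (half-open, `[lo, hi)`); the open-topped
#' last bin as `"lo+"`.
#'
#' @param scheme a [size_class_scheme()].
#' @return character vector of bin labels.
#' @export
census_bin_labels <- function(scheme) {
  b <- scheme$census_breaks
  n <- length(b) - 1L
  lab <- paste0(b[-length(b)], "-", b[-1])
  lab[n] <- paste0(b[n], "+")
  lab
}

#' Parse census-bin labels to numeric intervals
#'
#' Accepts the package's own dialect (`"40-50"`, `"60+"`) plus the interval
#' spellings `"[40,50)"` and `">=60"`.
#'
#' @param labels character vector of bin labels.
#' @return a data frame with columns `label`, `lower`, `upper`.
#' @export
parse_bin_labels <- function(labels) {
  lab <- trimws(labels)
  lower <- upper <- rep(NA_real_, length(lab))
  rng <- regmatches(lab, regexec("^\\[?([0-9.]+)[-,]([0-9.]+)\\)?$", lab))
  opn <- regmatches(lab, regexec("^(?:([0-9.]+)\\+|>=\\s*([0-9.]+))$", lab))
  for (i in seq_along(lab)) {
    if (length(rng[[i]]) == 3) {
      lower[i] <- as.numeric(rng[[i]][2])
      upper[i] <- as.numeric(rng[[i]][3])
    } else if (length(opn[[i]]) == 3) {
      lower[i] <- as.numeric(opn[[i]][2])
      if (is.na(lower[i])) lower[i] <- as.numeric(opn[[i]][3])
      upper[i] <- Inf
    }
  }
  if (anyNA(lower)) {
    abort_schema(sprintf(
      "unrecognized size-bin labels: %s",
      paste(lab[is.na(lower)], collapse = ", ")
    ))
  }
  data.frame(label = labels, lower = lower, upper = upper)
}

match_bins_to_scheme <- function(labels, scheme) {
  parsed <- parse_bin_labels(labels)
  b <- scheme$census_breaks
  idx <- match(parsed$lower, b[-length(b)])
  ok <- !is.na(idx) & parsed$upper == b[idx + 1L]
  if (!all(ok)) {
    abort_schema(sprintf(
      "size-bin labels do not match the configured census bins: %s",
      paste(labels[!ok], collapse = ", ")
    ))
  }
  census_bin_labels(scheme)[idx]
}

#' Pipeline configuration
#'
#' Bundles the size-class scheme, presentation-rounding convention,
#' spawning-event detection parameters and the fertility success threshold.
#' All cascade arithmetic is carried at full precision; `pct_digits` /
#' `gg_digits` only control the rounded presentation columns (half-up).
#'
#' @param scheme a [size_class_scheme()].
#' @param pct_digits decimals for percentages in reports (default 1).
#' @param gg_digits decimals for gamete-output quantities, g g^-1 scale
#'   (default 2).
#' @param min_drop minimum relative GSI drop (%) from peak to trough for a
#'   decline to count as a spawning event (default 30).
#' @param min_rise minimum relative rise (%) above the running minimum for a
#'   local maximum to qualify as a spawning peak; defaults to `min_drop`.
#'   See [detect_events()].
#' @param min_range_drop minimum size of an event's absolute GSI drop as a
#'   percentage of the stratum's annual GSI range (max - min of the monthly
#'   means; default 30). Anchors events to the year's major excursion and
#'   rejects month-to-month noise wiggles; see [detect_events()].
#' @param min_span minimum event duration in calendar months (default 1).
#' @param interpolate_gaps if `TRUE`, single-month gaps in a GSI series are
#'   filled by linear interpolation before event detection. Off by default:
#'   missing months are simply skipped.
#' @param fertility_threshold minimum percentage of fertilized eggs for an
#'   assay to count as successful (default 80, inclusive).
#' @param se_unit unit across which density standard errors are computed:
#'   `"replicate"` (the survey's replicate blocks; default) or `"quadrat"`.
#' @param pool_sexes pool females and males in monthly GSI means (default
#'   `TRUE`).
#' @param quadrat_area default quadrat area in m^2 when absent from input
#'   (default 0.25, a 50 x 50 cm frame).
#' @param seed optional integer seed recorded in run logs.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = size_class_scheme(),
                            pct_digits = 1,
                            gg_digits = 2,
                            min_drop = 30,
                            min_rise = min_drop,
                            min_range_drop = 30,
                            min_span = 1,
                            interpolate_gaps = FALSE,
                            fertility_threshold = 80,
                            se_unit = c("replicate", "quadrat"),
                            pool_sexes = TRUE,
                            quadrat_area = 0.25,
                            seed = NULL) {
  if (!inherits(scheme, "size_class_scheme")) {
    abort_config("scheme must be a size_class_scheme()")
  }
  for (thr in c(min_drop, min_rise, min_range_drop, fertility_threshold)) {
    if (!is.numeric(thr) || length(thr) != 1 || thr <= 0 || thr > 100) {
      abort_config("thresholds must be single numbers in (0, 100]")
    }
  }
  if (pct_digits < 0 || gg_digits < 0) abort_config("digits must be >= 0")
  if (min_span < 0) abort_config("min_span must be >= 0")
  if (quadrat_area <= 0) abort_config("quadrat_area must be > 0")
  structure(
    list(
      scheme = scheme,
      pct_digits = pct_digits,
      gg_digits = gg_digits,
      min_drop = min_drop,
      min_rise = min_rise,
      min_range_drop = min_range_drop,
      min_span = min_span,
      interpolate_gaps = interpolate_gaps,
      fertility_threshold = fertility_threshold,
      se_unit = match.arg(se_unit),
      pool_sexes = pool_sexes,
      quadrat_area = quadrat_area,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys take the
#' defaults. The size-class scheme is given under `scheme` with keys
#' `census_breaks` (use `"Inf"` for the open top), `class_names`,
#' `class_lower`, `class_upper`, `class_fertile`, `min_landing_size`.
#'
#' @param path path to a JSON file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch_args <- raw$scheme
  if (!is.null(sch_args)) {
    num <- function(x) if (is.null(x)) NULL else as.numeric(x)
    sch <- do.call(size_class_scheme, Filter(Negate(is.null), list(
      census_breaks = num(sch_args$census_breaks),
      class_names = sch_args$class_names,
      class_lower = num(sch_args$class_lower),
      class_upper = num(sch_args$class_upper),
      class_fertile = sch_args$class_fertile,
      min_landing_size = sch_args$min_landing_size,
      td_bounds = num(sch_args$td_bounds)
    )))
  } else {
    sch <- size_class_scheme()
  }
  args <- raw[setdiff(names(raw), "scheme")]
  keep <- intersect(names(args), names(formals(pipeline_config)))
  do.call(pipeline_config, c(list(scheme = sch), args[keep]))
}
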