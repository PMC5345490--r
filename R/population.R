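#' Per-bin densities and size-frequency from quadrat censuses
#'
#' Mean density per census bin is the ratio of totals — total count across
#' quadrats divided by total quadrat area — which is unbiased under unequal
#' quadrat areas. The standard error is computed across replicate blocks
#' (each area's replicate survey units, the grain at which the census design
#' replicates), or per quadrat when `config$se_unit = "quadrat"`.
#' Frequencies are densities as percentages of the zone total; with an
#' all-zero census they are reported as 0 with a warning.
#'
#' @param quadrats a tibble from [read_quadrat_counts()] (or
#'   [simulate_quadrats()]).
#' @param config a [pipeline_config()].
#' @param zone optional zone filter; by default all zones present.
#' @return a tibble `zone, bin, mean_density, se_density, frequency_pct,
#'   total_density, surveyed_area` with one row per (zone, census bin); the
#'   two last columns repeat the zone-level totals.
#' @export
quadrat_densities <- function(quadrats, config = pipeline_config(),
                              zone = NULL) {
  if (!is.null(zone)) quadrats <- quadrats[quadrats$zone %in% zone, , drop = FALSE]
  if (nrow(quadrats) == 0) abort_domain("no quadrats for the requested zone")
  bins <- census_bin_labels(config$scheme)
  # bins with no column were never counted: zero-fill them
  for (b in setdiff(bins, names(quadrats))) quadrats[[b]] <- 0
  block <- if (config$se_unit == "quadrat") {
    quadrats$quadrat_id
  } else {
    paste(quadrats$area, quadrats$replicate, sep = "/")
  }
  quadrats$._block <- block

  per_zone <- lapply(split(quadrats, quadrats$zone), function(qz) {
    total_area <- sum(qz$area_m2)
    if (total_area <= 0) abort_domain("zero surveyed area")
    dens <- vapply(bins, function(b) sum(qz[[b]]) / total_area, numeric(1))
    se <- vapply(bins, function(b) {
      bl_count <- tapply(qz[[b]], qz$._block, sum)
      bl_area <- tapply(qz$area_m2, qz$._block, sum)
      d <- bl_count / bl_area
      if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0
    }, numeric(1))
    total <- sum(dens)
    freq <- if (total > 0) {
      100 * dens / total
    } else {
      rlang::warn(sprintf(
        "zone %s: census is empty; frequencies reported as 0", qz$zone[1]
      ))
      rep(0, length(dens))
    }
    tibble::tibble(
      zone = qz$zone[1], bin = bins,
      mean_density = unname(dens), se_density = unname(se),
      frequency_pct = unname(freq),
      total_density = total, surveyed_area = total_area
    )
  })
  dplyr::bind_rows(per_zone)
}

#' Densities of the named fertility classes
#'
#' Census-bin densities are summed into the named classes of the scheme
#' (e.g. `US` = bin `[40,50)`; `CS` = all bins at or above the landing
#' size). Census bins must align with class boundaries — a bin straddling a
#' class edge is a configuration error.
#'
#' @param density_table output of [quadrat_densities()].
#' @param scheme a [size_class_scheme()].
#' @return a tibble `zone, size_class, density, fertile`.
#' @export
fertile_class_density <- function(density_table, scheme = size_class_scheme()) {
  bins <- parse_bin_labels(unique(density_table$bin))
  cl <- scheme$classes
  straddle <- vapply(seq_len(nrow(bins)), function(i) {
    any(bins$lower[i] < cl$lower & bins$upper[i] > cl$lower) ||
      any(bins$lower[i] < cl$upper & bins$upper[i] > cl$upper)
  }, logical(1))
  if (any(straddle)) {
    abort_config(sprintf(
      "census bin(s) straddle a named-class boundary: %s",
      paste(bins$label[straddle], collapse = ", ")
    ))
  }
  out <- lapply(split(density_table, density_table$zone), function(dz) {
    parsed <- parse_bin_labels(dz$bin)
    dens <- vapply(seq_len(nrow(cl)), function(i) {
      inside <- parsed$lower >= cl$lower[i] & parsed$upper <= cl$upper[i]
      sum(dz$mean_density[inside])
    }, numeric(1))
    tibble::tibble(
      zone = dz$zone[1], size_class = cl$name,
      density = dens, fertile = cl$fertile
    )
  })
  dplyr::bind_rows(out)
}

#' Size-frequency distribution
#'
#' Bin frequency = 100 x bin density / total density, per zone.
#'
#' @param density_table output of [quadrat_densities()].
#' @return a tibble `zone, bin, frequency_pct`.
#' @export
size_frequency <- function(density_table) {
  out <- lapply(split(density_table, density_table$zone), function(dz) {
    total <- sum(dz$mean_density)
    if (total <= 0) abort_domain(sprintf("zone %s: total density is 0", dz$zone[1]))
    tibble::tibble(
      zone = dz$zone[1], bin = dz$bin,
      frequency_pct = 100 * dz$mean_density / total
    )
  })
  dplyr::bind_rows(out)
}
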