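#' Specification of one stratum's annual GSI cycle
#'
#' The latent monthly mean GSI follows a piecewise-linear trajectory:
#' from a baseline at the start of the series it builds up linearly to each
#' spawning window's peak and declines linearly to its trough; successive
#' windows chain (the next build-up starts from the previous trough). This
#' build-up/abrupt-decline shape matches observed annual GSI trends and
#' keeps the pre- and post-spawning months unambiguous. Individual GSI
#' values are drawn around the latent mean with a common standard deviation
#' and truncated at zero.
#'
#' @param zone,size_class stratum labels.
#' @param windows a data frame with one row per spawning window: columns
#'   `build_start`, `peak_month`, `trough_month` (`"YYYY-MM"`) and
#'   `peak_mean`, `trough_mean` (%); may have zero rows for a flat cycle.
#' @param baseline_mean latent mean (%) before the first build-up.
#' @param individual_sd standard deviation (%) of individual GSI around the
#'   monthly latent mean.
#' @param td_range test-diameter range (mm) individuals are drawn from,
#'   uniformly.
#' @return an object of class `gsi_cycle_spec`.
#' @export
gsi_cycle_spec <- function(zone, size_class, windows,
                           baseline_mean = 1, individual_sd = 0.8,
                           td_range = c(40, 50)) {
  windows <- tibble::as_tibble(windows)
  if (nrow(windows) > 0) {
    assert_ym(c(windows$build_start, windows$peak_month, windows$trough_month))
    if (any(windows$peak_mean <= windows$trough_mean) ||
        any(windows$trough_mean < 0)) {
      abort_config("each window needs peak_mean > trough_mean >= 0")
    }
    bs <- ym_index(windows$build_start)
    pk <- ym_index(windows$peak_month)
    tr <- ym_index(windows$trough_month)
    if (any(bs > pk) || any(pk >= tr)) {
      abort_config("each window needs build_start <= peak_month < trough_month")
    }
    if (nrow(windows) > 1 && any(bs[-1] < tr[-length(tr)])) {
      abort_config("windows must be time-ordered and non-overlapping")
    }
  }
  if (baseline_mean < 0 || individual_sd < 0) {
    abort_config("baseline_mean and individual_sd must be >= 0")
  }
  structure(
    list(
      zone = zone, size_class = size_class, windows = windows,
      baseline_mean = baseline_mean, individual_sd = individual_sd,
      td_range = td_range
    ),
    class = "gsi_cycle_spec"
  )
}

#' Latent monthly mean GSI of a cycle spec
#'
#' @param spec a [gsi_cycle_spec()].
#' @param months months (`"YYYY-MM"`) to evaluate.
#' @return numeric vector of latent means (%).
#' @export
latent_gsi <- function(spec, months) {
  assert_ym(months)
  xi <- ym_index(months)
  w <- spec$windows
  if (nrow(w) == 0) return(rep(spec$baseline_mean, length(months)))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(w))) {
    start_val <- if (i == 1) spec$baseline_mean else w$trough_mean[i - 1]
    kx <- c(kx, ym_index(w$build_start[i]), ym_index(w$peak_month[i]),
            ym_index(w$trough_month[i]))
    ky <- c(ky, start_val, w$peak_mean[i], w$trough_mean[i])
  }
  # duplicate knot positions (build_start == peak, or chained windows)
  # collapse to the later-listed value, so the peak value wins
  ord <- order(kx, seq_along(kx))
  kx <- kx[ord]; ky <- ky[ord]
  dup <- duplicated(kx)
  if (any(dup)) { ky <- ky[!duplicated(kx, fromLast = TRUE)]; kx <- kx[!dup] }
  stats::approx(kx, ky, xout = xi, rule = 2)$y
}

#' Simulate individual urchin records from GSI cycle specs
#'
#' For each stratum and month, `n_per_month` individuals are generated:
#' GSI is drawn normally around the latent mean (truncated at 0), the test
#' diameter uniformly within the stratum's TD range, total wet weight from
#' the allometry TW = a x TD^b, and gonad weight back-derived as
#' GSI/100 x TW — so the generator's ground truth is expressed in the same
#' statistic the pipeline estimates.
#'
#' @param specs a [gsi_cycle_spec()] or list of them.
#' @param n_per_month individuals per stratum per month (default 8).
#' @param months sampled months (default June 2013 to May 2014).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param allometry_a,allometry_b allometric constants (g, mm^-b); generator
#'   conveniences, roughly matching a 50-mm urchin of ~40 g.
#' @return a tibble in the `urchins.csv` schema.
#' @export
simulate_gsi_records <- function(specs, n_per_month = 8,
                                 months = month_seq("2013-06", "2014-05"),
                                 seed = NULL,
                                 allometry_a = 5e-4, allometry_b = 2.9) {
  if (inherits(specs, "gsi_cycle_spec")) specs <- list(specs)
  if (n_per_month < 1) abort_config("n_per_month must be >= 1")
  if (allometry_a <= 0 || allometry_b <= 2 || allometry_b >= 3.5) {
    abort_config("allometry must have a > 0 and b in (2, 3.5)")
  }
  gen <- function() {
    rows <- lapply(specs, function(sp) {
      mu <- latent_gsi(sp, months)
      per_month <- lapply(seq_along(months), function(j) {
        gsi <- pmax(0, stats::rnorm(n_per_month, mu[j], sp$individual_sd))
        td <- stats::runif(n_per_month, sp$td_range[1], sp$td_range[2])
        tw <- allometry_a * td^allometry_b
        tibble::tibble(
          record_id = sprintf(
            "%s-%s-%s-%02d", sp$zone, sp$size_class, months[j],
            seq_len(n_per_month)
          ),
          zone = sp$zone, area = paste0(sp$zone, "-A1"), month = months[j],
          td_mm = td, tw_g = tw, gw_g = gsi / 100 * tw,
          sex = rep_len(c("F", "M"), n_per_month)
        )
      })
      dplyr::bind_rows(per_month)
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Specification of a zone's population for quadrat simulation
#'
#' @param zone zone label.
#' @param densities named numeric vector of true densities (ind m^-2), one
#'   per census-bin label.
#' @param quadrats_per_area quadrats laid per area (split evenly into two
#'   replicate blocks).
#' @param areas number of areas in the zone.
#' @param quadrat_area quadrat area in m^2 (default 0.25).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(zone, densities, quadrats_per_area = 100,
                            areas = 2, quadrat_area = 0.25) {
  if (any(densities < 0)) abort_config("densities must be >= 0")
  if (is.null(names(densities))) abort_config("densities must be named by bin")
  if (quadrats_per_area < 1 || areas < 1 || quadrat_area <= 0) {
    abort_config("quadrats_per_area, areas >= 1 and quadrat_area > 0 required")
  }
  structure(
    list(
      zone = zone, densities = densities,
      quadrats_per_area = quadrats_per_area, areas = areas,
      quadrat_area = quadrat_area
    ),
    class = "population_spec"
  )
}

#' Simulate quadrat census counts
#'
#' Counts per quadrat and bin are Poisson with mean density x quadrat area.
#' With `deterministic = TRUE` the Poisson draw is replaced by its
#' expectation (possibly non-integer), which makes the downstream density
#' estimates reproduce the spec's densities exactly — the zero-noise limit
#' used in end-to-end identity checks.
#'
#' @param spec a [population_spec()] or list of them.
#' @param seed optional integer seed.
#' @param deterministic replace Poisson draws by expected counts.
#' @return a tibble in the `quadrats.csv` schema.
#' @export
simulate_quadrats <- function(spec, seed = NULL, deterministic = FALSE) {
  if (inherits(spec, "population_spec")) spec <- list(spec)
  gen <- function() {
    rows <- lapply(spec, function(sp) {
      nq <- sp$quadrats_per_area * sp$areas
      area_id <- rep(paste0(sp$zone, "-A", seq_len(sp$areas)),
                     each = sp$quadrats_per_area)
      replicate <- rep(rep(c("R1", "R2"),
                           length.out = sp$quadrats_per_area), sp$areas)
      out <- tibble::tibble(
        zone = sp$zone, area = area_id,
        quadrat_id = sprintf("%s-Q%04d", sp$zone, seq_len(nq)),
        replicate = replicate, area_m2 = sp$quadrat_area
      )
      for (b in names(sp$densities)) {
        lambda <- sp$densities[[b]] * sp$quadrat_area
        out[[b]] <- if (deterministic) {
          rep(lambda, nq)
        } else {
          stats::rpois(nq, lambda)
        }
      }
      out
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate fertility assays
#'
#' Fertilized-egg counts are binomial draws with probability `p_fert`;
#' pluteus counts likewise with `p_pluteus` (skipped when `n_larvae` is
#' `NA`, emulating assays where no larval count was done).
#'
#' @param p_fert probability an egg is fertilized, in `[0, 1]`.
#' @param n_eggs eggs scored per assay (>= 1).
#' @param months assay months (one assay per month).
#' @param zone,size_class labels attached to the assays.
#' @param p_pluteus probability a larva reaches the four-arm pluteus stage.
#' @param n_larvae larvae scored per assay (`NA` to skip larval counts).
#' @param seed optional integer seed.
#' @return a tibble in the `fertility.csv` schema.
#' @export
simulate_fertility <- function(p_fert, n_eggs,
                               months = month_seq("2013-12", "2014-04"),
                               zone = "HP", size_class = "US",
                               p_pluteus = 0.97, n_larvae = 100,
                               seed = NULL) {
  if (p_fert < 0 || p_fert > 1) abort_config("p_fert must be in [0, 1]")
  if (n_eggs < 1) abort_config("n_eggs must be >= 1")
  gen <- function() {
    k <- length(months)
    tibble::tibble(
      zone = zone, month = months, size_class = size_class,
      eggs_total = n_eggs,
      eggs_fertilized = stats::rbinom(k, n_eggs, p_fert),
      plutei_scored = if (is.na(n_larvae)) {
        NA_real_
      } else {
        as.numeric(stats::rbinom(k, n_larvae, p_pluteus))
      },
      plutei_total = if (is.na(n_larvae)) NA_real_ else as.numeric(n_larvae)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# ---- built-in scenarios -------------------------------------------------

#' Built-in GSI cycle specs of the two study-like scenarios
#'
#' Latent cycle anchors for a heavily harvested zone (`"hp"`: one
#' late-winter spawning event per fertile class) and a protected zone
#' (`"lp"`: two events per year). Peak/trough anchors follow the field
#' summary shipped as [example_summary()]; the non-fertile `Small-US` class
#' cycles flat below 1%.
#'
#' @param scenario `"hp"` or `"lp"`.
#' @param individual_sd individual GSI standard deviation (%).
#' @return a list of [gsi_cycle_spec()] objects (CS, US, Small-US).
#' @export
scenario_cycle_specs <- function(scenario = c("hp", "lp"),
                                 individual_sd = 0.8) {
  scenario <- match.arg(scenario)
  win <- function(bs, pk, tr, pm, tm) {
    tibble::tibble(
      build_start = bs, peak_month = pk, trough_month = tr,
      peak_mean = pm, trough_mean = tm
    )
  }
  if (scenario == "hp") {
    list(
      gsi_cycle_spec("HP", "CS",
        win("2013-06", "2014-03", "2014-05", 6.6, 1.6),
        baseline_mean = 1.6, individual_sd = individual_sd,
        td_range = c(50, 70)
      ),
      gsi_cycle_spec("HP", "US",
        win("2013-06", "2014-03", "2014-05", 4.4, 1.3),
        baseline_mean = 1.3, individual_sd = individual_sd,
        td_range = c(40, 50)
      ),
      gsi_cycle_spec("HP", "Small-US", tibble::tibble(),
        baseline_mean = 0.6, individual_sd = individual_sd,
        td_range = c(30, 40)
      )
    )
  } else {
    list(
      gsi_cycle_spec("LP", "CS",
        dplyr::bind_rows(
          win("2013-06", "2013-06", "2013-12", 6.7, 2.5),
          win("2013-12", "2014-02", "2014-04", 5.4, 2.5)
        ),
        baseline_mean = 6.7, individual_sd = individual_sd,
        td_range = c(50, 70)
      ),
      gsi_cycle_spec("LP", "US",
        dplyr::bind_rows(
          win("2013-06", "2013-06", "2013-12", 5.2, 1.0),
          win("2013-12", "2014-02", "2014-05", 4.0, 1.2)
        ),
        baseline_mean = 5.2, individual_sd = individual_sd,
        td_range = c(40, 50)
      ),
      gsi_cycle_spec("LP", "Small-US", tibble::tibble(),
        baseline_mean = 0.6, individual_sd = individual_sd,
        td_range = c(30, 40)
      )
    )
  }
}

#' Built-in population specs of the two study-like scenarios
#'
#' True per-bin densities (ind m^-2). Bin totals match the zones' census
#' summaries: total 10 with the commercial class at 6% of the population in
#' the harvested zone; total 5.4, adult-dominated, in the protected zone.
#'
#' @param scenario `"hp"` or `"lp"`.
#' @param quadrats_per_area,areas census effort (default 100 x 2).
#' @return a [population_spec()].
#' @export
scenario_population_spec <- function(scenario = c("hp", "lp"),
                                     quadrats_per_area = 100, areas = 2) {
  scenario <- match.arg(scenario)
  dens <- if (scenario == "hp") {
    c("0-10" = 0.85, "10-20" = 0.85, "20-30" = 2.0, "30-40" = 3.0,
      "40-50" = 2.7, "50-60" = 0.6, "60+" = 0)
  } else {
    c("0-10" = 0.55, "10-20" = 0.55, "20-30" = 0.6, "30-40" = 0.6,
      "40-50" = 0.4, "50-60" = 0.9, "60+" = 1.8)
  }
  population_spec(
    zone = toupper(scenario), densities = dens,
    quadrats_per_area = quadrats_per_area, areas = areas
  )
}

scenario_truth <- function(cycle_specs, pop_spec) {
  dens <- pop_spec$densities
  parsed <- parse_bin_labels(names(dens))
  class_density <- function(size_class) {
    cl <- size_class_scheme()$classes
    i <- match(size_class, cl$name)
    sum(dens[parsed$lower >= cl$lower[i] & parsed$upper <= cl$upper[i]])
  }
  per_class <- lapply(cycle_specs, function(sp) {
    w <- sp$windows
    if (nrow(w) == 0) return(NULL)
    igo <- individual_gamete_output(w$peak_mean, w$trough_mean)
    d <- class_density(sp$size_class)
    go <- gamete_output_per_m2(igo, d)
    ct <- class_totals(go)
    tibble::tibble(
      zone = sp$zone, size_class = sp$size_class,
      event = seq_len(nrow(w)),
      start_month = w$peak_month, end_month = w$trough_month,
      pre_gsi = w$peak_mean, post_gsi = w$trough_mean,
      igo = igo,
      magnitude = spawning_magnitude(w$peak_mean, w$trough_mean),
      density = d, go = go, tgo = ct$tgo, mgo = ct$mgo,
      fertile = size_class_scheme()$classes$fertile[
        match(sp$size_class, size_class_scheme()$classes$name)
      ]
    )
  })
  per_class <- dplyr::bind_rows(per_class)
  fert <- per_class[per_class$fertile, , drop = FALSE]
  pop <- population_totals(dplyr::distinct(
    fert[c("zone", "size_class", "tgo", "mgo")]
  ))
  list(
    classes = per_class,
    densities = as.list(dens),
    total_density = sum(dens),
    pop_tgo = pop$pop_tgo,
    pop_mgo = pop$pop_mgo
  )
}

#' Simulate a complete study scenario
#'
#' Generates the three pipeline inputs — individual records, quadrat counts
#' and fertility assays — for one of the built-in scenarios: `"hp"`, a
#' heavily harvested zone with a single late-winter spawning event and the
#' commercial class reduced to ~6% of the population, or `"lp"`, a protected
#' zone with two spawning events per year and an adult-dominated size
#' structure. All latent parameters are returned as ground truth. With the
#' same seed and arguments the output is identical, byte for byte, when
#' written.
#'
#' @param scenario `"hp"` or `"lp"`.
#' @param seed integer seed driving all randomness.
#' @param dir optional directory; when given, writes `urchins.csv`,
#'   `quadrats.csv`, `fertility.csv` and `truth.json` there.
#' @param n_per_month individuals sampled per stratum per month (default 8).
#' @param individual_sd individual GSI standard deviation (%; default 0.8).
#' @param quadrats_per_area quadrats per area (default 100; two areas).
#' @param p_fert fertilization probability of the assays (default 0.92,
#'   mid-range of observed assay outcomes).
#' @param deterministic zero-noise limit: latent GSI means exactly and
#'   expected (non-integer) quadrat counts; fertility counts at expectation.
#' @return a list with `urchins`, `quadrats`, `fertility`, `truth`.
#' @export
simulate_scenario <- function(scenario = c("hp", "lp"), seed = 1, dir = NULL,
                              n_per_month = 8, individual_sd = 0.8,
                              quadrats_per_area = 100, p_fert = 0.92,
                              deterministic = FALSE) {
  scenario <- match.arg(scenario)
  if (deterministic) individual_sd <- 0
  specs <- scenario_cycle_specs(scenario, individual_sd = individual_sd)
  pop <- scenario_population_spec(scenario, quadrats_per_area = quadrats_per_area)
  run <- function() {
    urchins <- simulate_gsi_records(specs, n_per_month = n_per_month)
    quadrats <- simulate_quadrats(pop, deterministic = deterministic)
    fertility <- if (deterministic) {
      tibble::tibble(
        zone = toupper(scenario), month = month_seq("2013-12", "2014-04"),
        size_class = "US", eggs_total = 400,
        eggs_fertilized = round(400 * p_fert),
        plutei_scored = 97, plutei_total = 100
      )
    } else {
      simulate_fertility(p_fert, 400, zone = toupper(scenario))
    }
    list(urchins = urchins, quadrats = quadrats, fertility = fertility)
  }
  out <- withr::with_seed(seed, run())
  out$truth <- c(
    scenario_truth(specs, pop),
    list(scenario = scenario, seed = seed, n_per_month = n_per_month,
         individual_sd = individual_sd, p_fert = p_fert)
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_table_csv(out$urchins, file.path(dir, "urchins.csv"))
    write_table_csv(out$quadrats, file.path(dir, "quadrats.csv"))
    write_table_csv(out$fertility, file.path(dir, "fertility.csv"))
    jsonlite::write_json(
      out$truth, file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  out
}
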