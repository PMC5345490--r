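series_tbl <- function(months, means, zone = "Z", size_class = "CS") {
  tibble::tibble(zone = zone, size_class = size_class, month = months,
                 mean_gsi = means, se_gsi = 0, n = 8L)
}

test_that("IGO is the GSI drop re-expressed as mass fraction", {
  expect_equal(individual_gamete_output(4.4, 1.3), 0.031)
  expect_equal(round_half_up(individual_gamete_output(4.4, 1.3), 2), 0.03)
  expect_equal(round_half_up(individual_gamete_output(6.6, 1.6), 2), 0.05)
  expect_error(individual_gamete_output(5.0, 5.0),
               class = "urchingo_domain_error")
  expect_error(individual_gamete_output(3, 4), class = "urchingo_domain_error")
})

test_that("spawning magnitude is the released fraction of the peak", {
  expect_equal(round_half_up(spawning_magnitude(4.4, 1.3), 1), 70.5)
  expect_equal(spawning_magnitude(4.0, 1.2), 70.0)
  for (p in c(0.5, 3, 8)) expect_equal(spawning_magnitude(p, 0), 100)
  expect_error(spawning_magnitude(0, 0), class = "urchingo_domain_error")
  expect_error(spawning_magnitude(2, 2), class = "urchingo_domain_error")
})

test_that("a single-peak year yields one event with the peak/trough means", {
  months <- month_seq("2013-06", "2014-05")
  means <- c(2.0, 2.5, 3.0, 3.6, 4.2, 4.8, 5.4, 5.9, 6.3, 6.6, 3.8, 1.3)
  ev <- detect_events(series_tbl(months, means))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_month, "2014-03")
  expect_equal(ev$end_month, "2014-05")
  expect_equal(ev$pre_gsi, 6.6)
  expect_equal(ev$post_gsi, 1.3)
})

test_that("a two-peak year yields two disjoint, time-ordered events", {
  months <- month_seq("2013-06", "2014-05")
  means <- c(6.7, 6.0, 5.3, 4.6, 3.9, 3.2, 2.5, 3.9, 5.4, 4.0, 2.5, 2.5)
  ev <- detect_events(series_tbl(months, means))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$pre_gsi, c(6.7, 5.4))
  expect_equal(ev$post_gsi, c(2.5, 2.5))
  expect_equal(ev$start_month, c("2013-06", "2014-02"))
  expect_equal(ev$end_month, c("2013-12", "2014-04")) # earliest tied trough
  expect_true(ev$end_month[1] < ev$start_month[2]) # disjoint in time
})

test_that("flat and monotone non-decreasing series yield no events", {
  months <- month_seq("2013-06", "2013-12")
  expect_equal(nrow(detect_events(series_tbl(months, rep(4, 7)))), 0)
  expect_equal(nrow(detect_events(series_tbl(months, seq(1, 4, length.out = 7)))), 0)
  expect_error(detect_events(series_tbl(months[1:2], c(5, 1))),
               class = "urchingo_domain_error") # < 3 months
})

test_that("sub-threshold declines are not events", {
  months <- month_seq("2013-06", "2014-01")
  # 20% relative drop: below the 30% default
  means <- c(4, 4.5, 5, 5, 5, 4.6, 4.2, 4.0)
  expect_equal(nrow(detect_events(series_tbl(months, means))), 0)
})

test_that("event statistics obey the magnitude-IGO consistency identity", {
  for (seed in 1:5) {
    sim <- simulate_scenario("lp", seed = seed)
    ev <- detect_events(gsi_monthly_series(sim$urchins))
    expect_gt(nrow(ev), 0)
    expect_equal(ev$magnitude, 100 * (100 * ev$igo) / ev$pre_gsi,
                 tolerance = 1e-12)
    expect_true(all(ev$pre_gsi > ev$post_gsi))
    expect_true(all(ev$start_month < ev$end_month))
  }
})

test_that("detection ignores non-extremal months: insertion and deletion", {
  months <- month_seq("2013-06", "2014-05")
  means <- c(6.7, 6.0, 5.3, 4.6, 3.9, 3.2, 2.5, 3.9, 5.4, 4.0, 2.5, 2.5)
  base <- detect_events(series_tbl(months, means))
  keep <- c("zone", "size_class", "start_month", "end_month",
            "pre_gsi", "post_gsi")

  # deleting a non-extremal month (the unsampled-November case)
  drop_nov <- series_tbl(months, means)[months != "2013-11", ]
  expect_equal(detect_events(drop_nov)[keep], base[keep])

  # removing any single non-extremal month leaves pre/post unchanged
  extremal <- c("2013-06", "2013-12", "2014-02", "2014-04")
  for (m in setdiff(months, c(extremal, "2014-05"))) {
    thinned <- series_tbl(months, means)[months != m, ]
    expect_equal(detect_events(thinned)[keep], base[keep])
  }
})

test_that("detection equals the brute-force oracle on short series", {
  cfg <- pipeline_config()
  withr::with_seed(31, {
    for (rep in 1:200) {
      n <- sample(3:12, 1)
      s <- random_series(n)
      if (rep %% 3 == 0) {
        # inject ties to exercise the earliest-month rule
        i <- sample(n - 1, 1)
        s$mean_gsi[i + 1] <- s$mean_gsi[i]
      }
      got <- detect_events(s, cfg)
      want <- oracle_detect(s$month, s$mean_gsi)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$start_month, want$start_month)
        expect_equal(got$end_month, want$end_month)
        expect_equal(got$pre_gsi, want$pre_gsi)
        expect_equal(got$post_gsi, want$post_gsi)
      }
    }
  })
})

test_that("single-month gaps can be interpolated on request", {
  cfg <- pipeline_config(interpolate_gaps = TRUE)
  months <- month_seq("2013-06", "2014-05")
  means <- c(2.0, 2.5, 3.0, 3.6, 4.2, 4.8, 5.4, 5.9, 6.3, 6.6, 3.8, 1.3)
  s <- series_tbl(months, means)[-5, ] # drop 2013-10
  ev <- detect_events(s, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$pre_gsi, 6.6)
})
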