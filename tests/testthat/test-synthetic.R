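test_that("the latent trajectory is piecewise linear between anchors", {
  sp <- gsi_cycle_spec(
    "HP", "CS",
    data.frame(build_start = "2013-06", peak_month = "2014-03",
               trough_month = "2014-05", peak_mean = 6.6, trough_mean = 1.3),
    baseline_mean = 1.6, individual_sd = 0
  )
  months <- month_seq("2013-06", "2014-05")
  mu <- latent_gsi(sp, months)
  expect_equal(mu[months == "2013-06"], 1.6)
  expect_equal(mu[months == "2014-03"], 6.6)
  expect_equal(mu[months == "2014-05"], 1.3)
  # linear in between: constant increments on each branch
  expect_equal(diff(mu[1:10]), rep((6.6 - 1.6) / 9, 9))
  flat <- gsi_cycle_spec("Z", "CS", data.frame()[0, ], baseline_mean = 2)
  expect_equal(latent_gsi(flat, months), rep(2, 12))
})

test_that("zero-noise records reproduce the latent trajectory exactly", {
  sp <- gsi_cycle_spec(
    "HP", "CS",
    data.frame(build_start = "2013-06", peak_month = "2014-03",
               trough_month = "2014-05", peak_mean = 6.6, trough_mean = 1.3),
    baseline_mean = 1.6, individual_sd = 0, td_range = c(50, 70)
  )
  rec <- simulate_gsi_records(sp, n_per_month = 4, seed = 3)
  s <- gsi_monthly_series(rec)
  mu <- latent_gsi(sp, s$month)
  expect_equal(s$mean_gsi, mu)
  expect_equal(s$se_gsi, rep(0, nrow(s)))
})

test_that("simulated records respect the record invariants", {
  sim <- simulate_scenario("lp", seed = 12)
  u <- sim$urchins
  expect_true(all(u$gw_g >= 0))
  expect_true(all(u$gw_g <= u$tw_g))
  expect_true(all(u$tw_g > 0))
  cls <- assign_size_class(u$td_mm)
  expect_true(all(!is.na(cls)))
  # GSI never negative thanks to truncation at zero
  expect_true(all(compute_gsi(u$gw_g, u$tw_g) >= 0))
})

test_that("identical seeds give identical outputs, different seeds differ", {
  a <- simulate_scenario("hp", seed = 5)
  b <- simulate_scenario("hp", seed = 5)
  c_ <- simulate_scenario("hp", seed = 6)
  expect_identical(a$urchins, b$urchins)
  expect_identical(a$quadrats, b$quadrats)
  expect_identical(a$fertility, b$fertility)
  expect_false(identical(a$urchins$gw_g, c_$urchins$gw_g))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_scenario("lp", seed = 9, dir = d1)
  simulate_scenario("lp", seed = 9, dir = d2)
  for (f in c("urchins.csv", "quadrats.csv", "fertility.csv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("quadrat counts are Poisson with mean density x area", {
  sp <- population_spec("Z", c("30-40" = 10), quadrats_per_area = 400,
                        areas = 1)
  q <- simulate_quadrats(sp, seed = 21)
  expect_equal(mean(q$`30-40`), 10 * 0.25, tolerance = 0.1)
  expect_equal(stats::var(q$`30-40`), 10 * 0.25, tolerance = 0.2)
  det <- simulate_quadrats(sp, deterministic = TRUE)
  expect_true(all(det$`30-40` == 2.5)) # expectation, not a draw
  zero <- simulate_quadrats(population_spec("Z", c("30-40" = 0),
                                            quadrats_per_area = 5), seed = 1)
  expect_true(all(zero$`30-40` == 0))
})

test_that("estimated total density falls within 3 SE of the truth", {
  sp <- scenario_population_spec("hp", quadrats_per_area = 100) # 200 quadrats
  truth_total <- sum(sp$densities)
  se <- sqrt(truth_total / (200 * 0.25))
  for (seed in c(2, 12, 22)) {
    d <- quadrat_densities(simulate_quadrats(sp, seed = seed))
    expect_lt(abs(unique(d$total_density) - truth_total), 3 * se)
  }
})

test_that("binomial fertility assays hit the success threshold as expected", {
  perfect <- simulate_fertility(1.0, 200, seed = 1)
  fs <- fertility_summary(perfect)
  expect_true(all(fs$fertilization_pct == 100))
  expect_true(all(fs$success))
  # p = 0.9, n = 400: success virtually certain; p = 0.5: failure ditto
  for (seed in 1:30) {
    hi <- fertility_summary(simulate_fertility(0.9, 400, months = "2014-01",
                                               seed = seed))
    lo <- fertility_summary(simulate_fertility(0.5, 400, months = "2014-01",
                                               seed = seed))
    expect_true(hi$success)
    expect_false(lo$success)
  }
})

test_that("zero-noise scenarios reproduce the reference cascade end to end", {
  want <- expected_zone_summary()
  for (sc in c("hp", "lp")) {
    sim <- simulate_scenario(sc, seed = 1, deterministic = TRUE)
    ser <- gsi_monthly_series(sim$urchins)
    ev <- detect_events(ser)
    dens <- fertile_class_density(quadrat_densities(sim$quadrats))
    rep <- build_report(ev, dens, sim$fertility)
    zone <- toupper(sc)
    expect_equal(report_cell(rep, zone, NA, NA, "pop_tgo"),
                 want$pop_tgo[[zone]])
    expect_equal(report_cell(rep, zone, NA, NA, "pop_mgo"),
                 want$pop_mgo[[zone]])
    for (cl in c("US", "CS")) {
      key <- paste(zone, cl, sep = "_")
      expect_equal(report_cell(rep, zone, cl, NA, "tgo"), want$tgo[[key]])
      expect_equal(report_cell(rep, zone, cl, NA, "mgo"), want$mgo[[key]])
      n_ev <- sum(rep$classes$zone == zone & rep$classes$size_class == cl)
      expect_equal(n_ev, if (sc == "hp") 1L else 2L)
      for (e in seq_len(n_ev)) {
        ekey <- if (sc == "hp") key else paste(key, e, sep = "_")
        expect_equal(report_cell(rep, zone, cl, e, "igo"), want$igo[[ekey]])
        expect_equal(report_cell(rep, zone, cl, e, "magnitude"),
                     want$magnitude[[ekey]])
        expect_equal(report_cell(rep, zone, cl, e, "go"), want$go[[ekey]])
      }
    }
  }
})

test_that("scenario ground truth matches the analytic cascade", {
  t_hp <- simulate_scenario("hp", seed = 1)$truth
  expect_equal(t_hp$pop_tgo, 0.1137)
  expect_equal(t_hp$pop_mgo, 0.1137)
  expect_equal(t_hp$total_density, 10)
  t_lp <- simulate_scenario("lp", seed = 1)$truth
  expect_equal(round_half_up(t_lp$pop_tgo, 2), 0.22)
  expect_equal(round_half_up(t_lp$pop_mgo, 2), 0.11)
  expect_equal(t_lp$total_density, 5.4)
})
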