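test_that("GO scales individual output by natural density", {
  expect_equal(gamete_output_per_m2(0.031, 2.7), 0.0837)
  expect_equal(round_half_up(gamete_output_per_m2(0.031, 2.7), 2), 0.08)
  expect_equal(gamete_output_per_m2(0.05, 0.6), 0.03)
  expect_equal(gamete_output_per_m2(0.07, 0), 0)
  expect_error(gamete_output_per_m2(-0.1, 1), class = "urchingo_domain_error")
})

test_that("TGO/MGO are sum and mean of per-event GO", {
  ct <- class_totals(c(0.1134, 0.0783))
  expect_equal(ct$tgo, 0.1917)
  expect_equal(round_half_up(ct$tgo, 2), 0.19)
  expect_equal(round_half_up(ct$mgo, 2), 0.10)
  one <- class_totals(0.0837)
  expect_equal(one$tgo, one$mgo) # single event: TGO = MGO
  expect_equal(class_totals(c(0, 0)), list(tgo = 0, mgo = 0))
  expect_error(class_totals(numeric(0)), class = "urchingo_domain_error")
})

test_that("population totals sum class TGOs and class MGOs", {
  hp <- tibble::tibble(tgo = c(0.0837, 0.03), mgo = c(0.0837, 0.03))
  pt <- population_totals(hp)
  expect_equal(round_half_up(pt$pop_tgo, 2), 0.11)
  expect_equal(round_half_up(pt$pop_mgo, 2), 0.11)
  lp <- tibble::tibble(tgo = c(0.028, 0.1917), mgo = c(0.014, 0.09585))
  pt2 <- population_totals(lp)
  expect_equal(round_half_up(pt2$pop_tgo, 2), 0.22)
  expect_equal(round_half_up(pt2$pop_mgo, 2), 0.11) # sum of class MGOs
  single <- population_totals(lp[1, ])
  expect_equal(single$pop_tgo, lp$tgo[1])
})

test_that("fertility success is inclusive at the threshold", {
  mk <- function(fert) tibble::tibble(
    zone = "HP", month = "2014-01", size_class = "US",
    eggs_total = 100, eggs_fertilized = fert,
    plutei_scored = NA_real_, plutei_total = NA_real_
  )
  expect_true(fertility_summary(mk(87))$success)
  expect_true(fertility_summary(mk(80))$success) # "at least 80%"
  expect_false(fertility_summary(mk(79))$success)
  with_larvae <- mk(90)
  with_larvae$plutei_scored <- 95
  with_larvae$plutei_total <- 100
  expect_equal(fertility_summary(with_larvae)$pluteus_pct, 95)
  expect_true(is.na(fertility_summary(mk(90))$pluteus_pct))
})

test_that("the full cascade reproduces the example-summary report", {
  rep <- report_from_summary(example_summary())
  want <- expected_zone_summary()
  expect_equal(report_cell(rep, "HP", "US", 1, "igo"), want$igo[["HP_US"]])
  expect_equal(report_cell(rep, "HP", "CS", 1, "igo"), want$igo[["HP_CS"]])
  expect_equal(report_cell(rep, "LP", "US", 1, "magnitude"),
               want$magnitude[["LP_US_1"]])
  expect_equal(report_cell(rep, "LP", "CS", 2, "magnitude"),
               want$magnitude[["LP_CS_2"]])
  expect_equal(report_cell(rep, "LP", "CS", 1, "go"), want$go[["LP_CS_1"]])
  expect_equal(report_cell(rep, "LP", "US", 2, "go"), want$go[["LP_US_2"]])
  expect_equal(report_cell(rep, "LP", "CS", NA, "tgo"), want$tgo[["LP_CS"]])
  expect_equal(report_cell(rep, "LP", "US", NA, "mgo"), want$mgo[["LP_US"]])
  expect_equal(report_cell(rep, "HP", NA, NA, "pop_tgo"), want$pop_tgo[["HP"]])
  expect_equal(report_cell(rep, "LP", NA, NA, "pop_tgo"), want$pop_tgo[["LP"]])
  expect_equal(report_cell(rep, "HP", NA, NA, "pop_mgo"), want$pop_mgo[["HP"]])
  expect_equal(report_cell(rep, "LP", NA, NA, "pop_mgo"), want$pop_mgo[["LP"]])
})

test_that("non-fertile classes never enter the report", {
  s <- example_summary()
  extra <- s[1, ]
  extra$size_class <- "Small-US"
  extra$pre_gsi <- 0.9
  extra$post_gsi <- 0.2
  extra$density <- 3.0
  rep <- report_from_summary(dplyr::bind_rows(s, extra))
  expect_false("Small-US" %in% rep$classes$size_class)
  expect_equal(report_cell(rep, "HP", NA, NA, "pop_tgo"), 0.11) # unchanged
})

test_that("a class failing the fertility gate is excluded from totals", {
  s <- example_summary()
  bad <- tibble::tibble(
    zone = "HP", month = c("2014-01", "2014-02", "2014-03"),
    size_class = "US", eggs_total = 100, eggs_fertilized = c(40, 50, 85),
    plutei_scored = NA_real_, plutei_total = NA_real_
  )
  ev <- s[c("zone", "size_class", "event", "start_month", "end_month",
            "pre_gsi", "post_gsi")]
  dens <- dplyr::distinct(s[c("zone", "size_class", "density")])
  expect_message(rep <- build_report(ev, dens, fertility = bad), "HP/US")
  expect_false(any(rep$classes$zone == "HP" & rep$classes$size_class == "US"))
  # HP total now carries only the CS class
  expect_equal(report_cell(rep, "HP", NA, NA, "pop_tgo"), 0.03)
  # passing assays leave the report unchanged
  good <- bad
  good$eggs_fertilized <- c(87, 92, 96)
  rep2 <- build_report(ev, dens, fertility = good)
  expect_equal(report_cell(rep2, "HP", NA, NA, "pop_tgo"), 0.11)
})

test_that("an event without a density row is a configuration error", {
  s <- example_summary()
  dens <- dplyr::distinct(s[c("zone", "size_class", "density")])
  expect_error(
    build_report(s[c("zone", "size_class", "event", "start_month",
                     "end_month", "pre_gsi", "post_gsi")],
                 dens[dens$size_class != "US", ]),
    class = "urchingo_config_error"
  )
})

test_that("GO is linear in density and IGO", {
  s <- example_summary()
  base <- report_from_summary(s)
  s2 <- s
  s2$density[s2$zone == "HP" & s2$size_class == "US"] <- 2 * 2.7
  doubled <- report_from_summary(s2)
  pick <- function(r) {
    r$classes[r$classes$zone == "HP" & r$classes$size_class == "US", ]
  }
  expect_equal(pick(doubled)$go, 2 * pick(base)$go)
  expect_equal(pick(doubled)$tgo, 2 * pick(base)$tgo)
  hp_cs_tgo <- base$classes$tgo[base$classes$zone == "HP" &
                                  base$classes$size_class == "CS"][1]
  expect_equal(
    doubled$population$pop_tgo[doubled$population$zone == "HP"],
    2 * pick(base)$tgo[1] + hp_cs_tgo
  )
})

test_that("population TGO conserves the event-level cascade", {
  rep <- report_from_summary(example_summary())
  direct <- example_summary() |>
    dplyr::mutate(contrib = (pre_gsi - post_gsi) / 100 * density) |>
    dplyr::group_by(zone) |>
    dplyr::summarise(pop_tgo = sum(contrib))
  expect_equal(rep$population$pop_tgo, direct$pop_tgo, tolerance = 1e-12)
})

test_that("rounding happens once, at presentation", {
  # full-precision path reproduces the published magnitude ...
  expect_equal(round_half_up(spawning_magnitude(4.4, 1.3), 1), 70.5)
  # ... while propagating a rounded IGO would not
  igo_rounded <- round_half_up(individual_gamete_output(4.4, 1.3), 2)
  expect_equal(round_half_up(100 * (100 * igo_rounded) / 4.4, 1), 68.2)
  # and the report's full-precision column is exact, not rounded
  rep <- report_from_summary(example_summary())
  tb <- rep$table
  full <- tb$value_full[tb$metric == "igo" & tb$zone == "HP" &
                          tb$size_class == "US"]
  expect_equal(full, 0.031, tolerance = 1e-15)
})
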