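mk_events <- function(site, year, n) {
  data.frame(site_id = site, date = date_from_doy365(year, seq(100, by = 7,
                                                               length.out = n)),
             scheme = "transect", stringsAsFactors = FALSE)
}
mk_counts <- function(events, species, positive) {
  n <- nrow(events)
  data.frame(site_id = events$site_id, species_id = species,
             date = events$date,
             count = c(rep(1L, positive), rep(0L, n - positive)),
             scheme = "transect", stringsAsFactors = FALSE)
}

test_that("population-year rule: 10+ events and 3+ positive events", {
  ev9 <- mk_events("s1", 2001, 9)
  ev10 <- mk_events("s1", 2002, 10)
  ev <- rbind(ev9, ev10)
  ct <- rbind(mk_counts(ev9, "spA", 9),    # 9 events, all positive
              mk_counts(ev10, "spB", 2),   # 10 events, 2 positive
              mk_counts(ev10, "spC", 3))   # boundary: 10 events, 3 positive
  rep <- select_population_years(ev, ct)
  expect_equal(nrow(rep), 3)
  get <- function(sp) rep[rep$species_id == sp, ]
  expect_false(get("spA")$included)
  expect_match(get("spA")$reasons, "events_lt_10")
  expect_false(get("spB")$included)
  expect_match(get("spB")$reasons, "positive_lt_3")
  expect_true(get("spC")$included)
  expect_identical(get("spC")$reasons, "")
  # counts referencing unknown events are an input error
  bad <- ct
  bad$date[1] <- as.Date("2003-06-01")
  expect_error(select_population_years(ev, bad), "events")
})

test_that("population rule: 15 fitted study years plus one pre-period year", {
  cr <- function(pop, years_ok) {
    data.frame(population_id = pop, species_id = "sp", site_id = pop,
               year = years_ok, scheme = "transect", fit_ok = TRUE,
               fail_reason = "none", first_peak_day = NA_integer_,
               trough_day = NA_integer_, intergenerational_ratio = NA_real_,
               stringsAsFactors = FALSE)
  }
  res <- select_populations(rbind(
    cr("p_ok", c(1985L, 1995:2009)),       # 15 study years + 1985
    cr("p_nopre", 1995:2014),              # 20 study years, no pre-period
    cr("p_14", c(1985L, 1995:2008))),      # 14 study years
    study_years = c(1995L, 2014L), pre_period = c(1980L, 1990L))
  expect_true(res$included[res$population_id == "p_ok"])
  expect_false(res$included[res$population_id == "p_nopre"])
  expect_match(res$reasons[res$population_id == "p_nopre"], "no_pre_period")
  expect_false(res$included[res$population_id == "p_14"])
  expect_match(res$reasons[res$population_id == "p_14"], "fitted_years_lt_15")
  # "recorded" mode accepts a pre-period year with a failed fit
  cr_rec <- cr("p_rec", c(1995:2009))
  cr_rec <- rbind(cr_rec, within(cr("p_rec", 1985L), fit_ok <- FALSE))
  expect_false(select_populations(cr_rec)$included)
  expect_true(select_populations(cr_rec, mode = "recorded")$included)
})

test_that("species rule: 3+ populations jointly covering all study years", {
  toy <- toy_selection_data()
  pop_rep <- select_populations(toy$curve_results)
  sp_rep <- select_species_from_populations(pop_rep, toy$coverage_counts)
  expect_true(sp_rep$included[sp_rep$species_id == "spA"])
  expect_false(sp_rep$included[sp_rep$species_id == "spB"])
  expect_match(sp_rep$reasons[sp_rep$species_id == "spB"], "populations_lt_3")
  expect_false(sp_rep$included[sp_rep$species_id == "spC"])
  expect_match(sp_rep$reasons[sp_rep$species_id == "spC"], "not_covered")
})

test_that("hectad rules: recording halves and median regional richness", {
  toy <- toy_selection_data()
  res <- select_heavily_recorded_hectads(toy$presences)
  rep <- res$report
  expect_equal(nrow(rep), 110)
  expect_equal(sum(rep$included), 108)
  expect_match(rep$reasons[rep$unit_id == "E000N000"], "halves")
  expect_match(rep$reasons[rep$unit_id == "E090N100"], "median_richness")
  expect_lt(rep$median_richness_pct[rep$unit_id == "E090N100"], 25)
  # fewer than 101 hectads: the neighbourhood is undefined
  small <- toy$presences[toy$presences$hectad_northing <= 40, ]
  expect_error(select_heavily_recorded_hectads(small), "101")
})

test_that("a fully recorded focal hectad attains 100% regional richness", {
  # 102 hectads in a line; the focal hectad records every species its
  # region records, every year
  grid <- data.frame(hectad_easting = seq(0L, by = 10L, length.out = 102L),
                     hectad_northing = 0L)
  yrs <- 1995:2014
  pres <- do.call(rbind, lapply(c("u", "v"), function(sp)
    data.frame(species_id = sp,
               hectad_easting = rep(grid$hectad_easting, length(yrs)),
               hectad_northing = 0L,
               year = rep(yrs, each = nrow(grid)))))
  res <- select_heavily_recorded_hectads(pres)
  expect_true(all(res$report$included))
  expect_true(all(res$report$median_richness_pct == 100))
})

test_that("distribution rules: hectad count, elevation, margin buffer", {
  toy <- toy_selection_data()
  heavy <- select_heavily_recorded_hectads(toy$presences)$heavy
  ph <- toy$presences[hectad_id(toy$presences$hectad_easting,
                                toy$presences$hectad_northing) %in%
                        heavy$hectad_id, ]
  rep <- select_species_distributions(ph, toy$elevations,
                                      margin_buffer = toy$margin_buffer)
  main <- rep[rep$level == "species_distribution", ]
  marg <- rep[rep$level == "margin_subset", ]
  expect_false(main$included[main$species_id == "sp2"])
  expect_match(main$reasons[main$species_id == "sp2"], "hectads_lt_20")
  expect_equal(main$n_heavy_hectads[main$species_id == "sp2"], 19L)
  expect_false(main$included[main$species_id == "sp3"])
  expect_match(main$reasons[main$species_id == "sp3"], "elevation")
  # sp4 is near the limit: out of the margin subset, kept in the main set
  expect_true(main$included[main$species_id == "sp4"])
  expect_false(marg$included[marg$species_id == "sp4"])
  expect_true(marg$included[marg$species_id == "sp5"])
  # missing elevations are an input error naming the hectads
  drop <- toy$elevations$easting == 10 & toy$elevations$northing == 0
  expect_error(select_species_distributions(ph, toy$elevations[!drop, ],
                                            margin_buffer = 40),
               "E010N000")
})

test_that("the cascade is idempotent and exhaustive", {
  toy <- toy_selection_data()
  r1 <- select_population_years(toy$events, toy$counts)
  r2 <- select_population_years(toy$events, toy$counts)
  expect_identical(r1, r2)
  # every population-year in the counts appears exactly once
  cts <- toy$counts
  cts$year <- as.integer(format(cts$date, "%Y"))
  units <- unique(paste(cts$site_id, cts$species_id, cts$year))
  expect_setequal(paste(r1$site_id, r1$species_id, r1$year), units)
  expect_equal(anyDuplicated(r1$unit_id), 0)

  h1 <- select_heavily_recorded_hectads(toy$presences)
  h2 <- select_heavily_recorded_hectads(toy$presences)
  expect_identical(h1, h2)
  expect_true(all(!h1$report$included | h1$report$reasons == ""))
  expect_true(all(h1$report$included | nzchar(h1$report$reasons)))
})
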