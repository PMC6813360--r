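mk_pop_metrics <- function(sites, years, phen = NULL, abund = NULL) {
  g <- expand.grid(site_id = sites, year = years, stringsAsFactors = FALSE)
  g$population_id <- paste(g$site_id, "sp", sep = ":")
  g$phenology_day <- if (is.null(phen)) 200 else phen(g)
  g$abundance_index <- if (is.null(abund)) 1 else abund(g)
  g
}

test_that("an exact linear phenology decline yields a positive advance", {
  m <- mk_pop_metrics(c("a", "b", "c"), 1995:2014,
                      phen = function(g) 200 - 0.5 * (g$year - 1995))
  tr <- suppressWarnings(species_trend(m, "phenology_advance", "sp"))
  expect_equal(tr$slope, 0.5, tolerance = 1e-8)
  expect_equal(tr$n_sites, 3L)
})

test_that("constant distribution series has zero trend", {
  d <- data.frame(species_id = "sp", year = 1995:2014, distribution_pct = 40,
                  margin_northing = 100)
  tr <- species_trend(d, "distribution_change", "sp")
  expect_equal(tr$slope, 0, tolerance = 1e-10)
})

test_that("an injected log-abundance trend is recovered within 2 SE", {
  set.seed(77)
  sites <- sprintf("s%02d", 1:10)
  site_eff <- rnorm(10, 0, 0.5)
  m <- mk_pop_metrics(sites, 1995:2014, abund = function(g)
    exp(log(5) + site_eff[match(g$site_id, sites)] +
          0.03 * (g$year - 2004.5) + rnorm(nrow(g), 0, 0.15)))
  tr <- species_trend(m, "abundance_change", "sp")
  expect_lt(abs(tr$slope - 0.03), 2 * tr$se)
})

test_that("zero abundance in an included year is surfaced as an error", {
  m <- mk_pop_metrics("a", 1995:2014)
  m$abundance_index[3] <- 0
  expect_error(species_trend(m, "abundance_change", "sp"), "zero abundance")
})

test_that("population trends are ordinary regressions with the sign flip", {
  m <- mk_pop_metrics("a", 1995:2014,
                      phen = function(g) 150 - 0.25 * (g$year - 1995))
  tr <- population_trend(m, "phenology_advance", "a:sp")
  expect_equal(tr$slope, 0.25, tolerance = 1e-8)

  m2 <- mk_pop_metrics("a", 1995:2014)
  tr2 <- population_trend(m2, "abundance_change", "a:sp")
  expect_equal(tr2$slope, 0)

  short <- mk_pop_metrics("a", 1995:1996)
  expect_true(is.na(population_trend(short, "abundance_change", "a:sp")$slope))
})

test_that("white-noise series give slope within 2 SE of zero ~95% of the time", {
  set.seed(55)
  hits <- 0L
  for (i in 1:1000) {
    d <- data.frame(site_id = "a", population_id = "a:sp", year = 1995:2014,
                    phenology_day = rnorm(20, 180, 5))
    tr <- population_trend(d, "phenology_advance", "a:sp")
    if (abs(tr$slope) < 2 * tr$se) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.93)
})

test_that("a single-site species trend equals the population trend", {
  set.seed(99)
  m <- mk_pop_metrics("a", 1995:2014,
                      abund = function(g) exp(rnorm(nrow(g), 1, 0.3)))
  sp <- species_trend(m, "abundance_change", "sp")
  pop <- population_trend(m, "abundance_change", "a:sp")
  expect_equal(sp$slope, pop$slope, tolerance = 1e-10)
  expect_equal(sp$se, pop$se, tolerance = 1e-10)
})

test_that("trend slopes are equivariant under year shifts and scaling", {
  set.seed(31)
  m <- mk_pop_metrics(c("a", "b"), 1995:2014,
                      abund = function(g) exp(rnorm(nrow(g), 1, 0.2)))
  t1 <- species_trend(m, "abundance_change", "sp")
  m_shift <- m
  m_shift$year <- m_shift$year + 100
  t2 <- species_trend(m_shift, "abundance_change", "sp")
  expect_equal(t1$slope, t2$slope, tolerance = 1e-6)
  # scaling abundance by a constant moves only the intercept of the log model
  m_scale <- m
  m_scale$abundance_index <- m_scale$abundance_index * 7
  t3 <- species_trend(m_scale, "abundance_change", "sp")
  expect_equal(t1$slope, t3$slope, tolerance = 1e-6)
})
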